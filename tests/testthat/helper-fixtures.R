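# Shared fixtures, all generated in code.

# small featurized panel, computed once per test session
panel_compounds <- function() {
  rbind(make_pfas_like_series("PFCA", 3:8),
        make_pfas_like_series("PFSA", 4:7),
        make_pfas_like_series("PFECA", 4:7))
}

.panel_cache <- new.env()
panel_descriptors <- function() {
  if (is.null(.panel_cache$dm))
    .panel_cache$dm <- featurize(panel_compounds())
  .panel_cache$dm
}

# planted matrix at the modelling problem's scale
planted_fixture <- function(seed = 3) {
  simulate_descriptor_matrix(planted_matrix_spec(seed = seed))
}

# synthetic raw luminescence plate: treated ratios rise with concentration
raw_plate <- function(sc_ratio = 1, fold = c(1, 2, 4), conc = c(1, 10, 100),
                      bio = 2, tech = 2, rluc = 50) {
  g <- expand.grid(tech_rep = 1:tech, bio_rep = 1:bio,
                   concentration = c(0, conc))
  f <- c(1, fold)[match(g$concentration, c(0, conc))]
  data.frame(compound_id = "cmp", concentration = g$concentration,
             bio_rep = g$bio_rep, tech_rep = g$tech_rep,
             fluc = sc_ratio * f * rluc, rluc = rluc)
}
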