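# Small in-code fixtures shared by several test files.

tiny_matrix <- function() {
  time_course_matrix(
    rbind(gA = c(0.1, -2.0, -1.0, 0.2),
          gB = c(0.0, 0.5, 1.5, 0.3),
          gC = c(0.0, 0.1, -0.1, 0.05)),
    times = c(0.5, 1, 4, 25))
}

write_tiny_tsv <- function(path = tempfile(fileext = ".tsv")) {
  write_expression(tiny_matrix(), path)
  path
}

# a reduced synthetic study for quick end-to-end runs
small_truth <- function(seed = 7L) {
  make_truth(n_genes = 400L,
             cluster_sizes = c(60L, 55L, 50L, 45L, 40L, 35L, 30L),
             n_decoys = 10L, n_go_decoys = 6L, seed = seed)
}

small_inputs <- function(seed = 7L, noise_sd = NULL, leak = NULL) {
  truth <- small_truth(seed)
  s <- regpulse:::derive_seeds(seed, 2L)
  x <- simulate_expression(truth,
                           noise_sd = if (is.null(noise_sd)) truth$noise_sd else noise_sd,
                           seed = s[1L])
  net <- simulate_network(truth, seed = s[2L],
                          leak = if (is.null(leak)) truth$leak else leak)
  list(truth = truth, x = x, net = net)
}
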