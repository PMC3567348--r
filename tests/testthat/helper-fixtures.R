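# Small in-code fixtures shared across the test files.

# A 2-sample, 2-replicate growth plate with constant blanks.
tiny_growth_plate <- function(blank = 0.05, times = seq(0, 24, by = 1)) {
  od <- rbind(rep(0.55, length(times)),
              rep(0.55, length(times)),
              rep(blank, length(times)))
  wells <- data.frame(well = c("A1", "A2", "B1"),
                      strain = c("WT", "WT", NA),
                      dose_uM = c(0, 0, 0),
                      replicate = c(1, 2, 1),
                      role = c("sample", "sample", "blank"))
  growth_curve_set(times, od, wells)
}

# A minimal array experiment: n_gene gene probes and n_null null features,
# every array built from a supplied signal function.
tiny_array_experiment <- function(n_gene = 200, n_null = 50,
                                  arrays = data.frame(
                                    array_id = c("T1", "C1"),
                                    dose_uM = c(100, 0),
                                    generations = 5,
                                    arm = c("treatment", "control"),
                                    replicate = 1),
                                  signal_fun = function(array_id) {
                                    c(rep(2^12, n_gene), rep(2^10, n_null))
                                  },
                                  ceiling = 2^15) {
  intens <- vapply(arrays$array_id, signal_fun, numeric(n_gene + n_null))
  probes <- data.frame(
    probe_id = c(sprintf("g%03d", 1:n_gene), sprintf("n%03d", 1:n_null)),
    gene_id = c(sprintf("GENE%03d", 1:n_gene), rep(NA_character_, n_null)),
    is_null_feature = rep(c(FALSE, TRUE), c(n_gene, n_null)))
  array_experiment(intens, probes, arrays, saturation_ceiling = ceiling)
}

# The shipped stress-library annotation fixtures.
stress_library_db <- function() {
  lib <- read_gmt(system.file("extdata", "stress_library_synthetic.gmt",
                              package = "fitscreen"))
  lib_genes <- lib$universe
  go <- read_gmt(system.file("extdata", "go_categories_synthetic.gmt",
                             package = "fitscreen"),
                 universe = lib_genes)
  activated <- readLines(system.file("extdata",
                                     "activated_orfs_10mgL_synthetic.txt",
                                     package = "fitscreen"))
  list(library = lib, go = go, activated = activated, lib_genes = lib_genes)
}

# Independent upper-tail hypergeometric oracle by complete enumeration of
# all C(N, n) draws (feasible for N <= 12).
hypergeom_tail_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_cat <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% in_cat) >= k))
}

# Independent upper binomial tail by enumeration of all 2^m outcome vectors.
binomial_tail_enum <- function(k, m, pi0) {
  outcomes <- expand.grid(rep(list(c(0, 1)), m))
  succ <- rowSums(outcomes)
  prob <- pi0^succ * (1 - pi0)^(m - succ)
  sum(prob[succ >= k])
}
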