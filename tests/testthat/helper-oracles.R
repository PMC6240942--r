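# Independent oracles and small builders shared across tests.

blosum62 <- function() {
  get(utils::data("BLOSUM62", package = "Biostrings",
                  envir = environment()))
}

# Exhaustive global-alignment oracle: recursively enumerates every global
# alignment of a and b and scores each path under affine gap penalties
# (gap of length L costs open + L * ext). Independent of any dynamic
# program; exponential, so only for short sequences.
brute_force_align_score <- function(a, b, mat = blosum62(), open = 10,
                                    ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > n && j > m) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= n && j <= m) {
      rec(i + 1L, j + 1L, score + mat[av[i], bv[j]], "m")
    }
    if (i <= n) {
      rec(i + 1L, j, score - ext - (if (state != "a") open else 0), "a")
    }
    if (j <= m) {
      rec(i, j + 1L, score - ext - (if (state != "b") open else 0), "b")
    }
  }
  rec(1L, 1L, 0, "m")
  best
}

random_peptide <- function(len, alphabet = c("A", "G", "K", "W")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Two-sided permutation p-value for a difference between two groups,
# using the Welch t statistic as the test statistic.
permutation_p <- function(a, b, n_perm = 1e5) {
  welch_t <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  }
  obs <- abs(welch_t(a, b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(welch_t(pool[idx], pool[-idx])) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# A 500-residue record with known motifs planted for variant tests:
# DDP at 473 and the SRS layout of the default family simulator.
planted_record <- function(id = "target", seed = 42) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- sample(aa, 500, replace = TRUE)
  res[357] <- "E"
  res[360] <- "R"
  res[473:475] <- c("D", "D", "P")
  protein_record(id, paste(res, collapse = ""))
}
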