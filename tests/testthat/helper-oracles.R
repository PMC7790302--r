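# Brute-force oracles and small model builders shared across tests.

# simple plus-strand gene with given exon lengths and fixed 100-bp introns
toy_model <- function(lens, poison_idx, start = 1000L, strand = "+",
                      gene_id = "toy", cds_start = 0L, sequence = NULL,
                      primers = NULL) {
  n <- length(lens)
  starts <- start + cumsum(c(0L, head(lens, -1) + 100L))
  exons <- tibble::tibble(
    exon_id = sprintf("e%02d", seq_len(n)),
    start = starts, end = starts + lens
  )
  if (strand == "-") {
    # keep rank order: highest coordinates first
    exons$start <- rev(exons$start)
    exons$end <- rev(exons$end)
  }
  gene_model(
    gene_id = gene_id, chrom = "chrT", strand = strand, exons = exons,
    poison_exon_id = sprintf("e%02d", poison_idx), primers = primers,
    sequence = sequence, cds_start = cds_start
  )
}

# per-base overlap counting by naive loop
brute_force_depth <- function(reads, region) {
  depth <- numeric(region$end - region$start)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != region$chrom) next
    for (p in seq(reads$start[i], reads$end[i] - 1L)) {
      if (p >= region$start && p < region$end) {
        depth[p - region$start + 1L] <- depth[p - region$start + 1L] + 1
      }
    }
  }
  depth
}

# naive per-exon read counting (a read counts once per exon it touches)
brute_force_exon_counts <- function(reads, model) {
  sapply(seq_len(nrow(model$exons)), function(i) {
    ex <- model$exons[i, ]
    ids <- character(0)
    for (j in seq_len(nrow(reads))) {
      overlaps <- reads$start[j] < ex$end && reads$end[j] > ex$start &&
        reads$chrom[j] == model$chrom
      if (overlaps) ids <- c(ids, reads$read_id[j])
    }
    length(unique(ids))
  })
}

# grid-search oracle for the steady-state fit: minimise squared residuals of
# the two model equations over a (psi, s) lattice, zooming three times
grid_fit_oracle <- function(psi_obs_wt, psi_obs_ki, psi_ki_allele = 1,
                            n_grid = 200) {
  f1 <- psi_obs_wt / 100
  f2 <- psi_obs_ki / 100
  frac <- function(psi1, psi2, s) {
    inc <- (psi1 + psi2) * s
    inc / (inc + (1 - psi1) + (1 - psi2))
  }
  lo <- c(psi = 0.001, s = 0.001)
  hi <- c(psi = 0.999, s = 0.999)
  for (zoom in 1:3) {
    grid <- expand.grid(
      psi = seq(lo["psi"], hi["psi"], length.out = n_grid),
      s = seq(lo["s"], hi["s"], length.out = n_grid)
    )
    loss <- (frac(grid$psi, grid$psi, grid$s) - f1)^2 +
      (frac(grid$psi, psi_ki_allele, grid$s) - f2)^2
    best <- grid[which.min(loss), ]
    step <- c(
      psi = (hi["psi"] - lo["psi"]) / (n_grid - 1),
      s = (hi["s"] - lo["s"]) / (n_grid - 1)
    )
    lo <- pmax(c(best$psi, best$s) - 10 * step, 1e-6)
    hi <- pmin(c(best$psi, best$s) + 10 * step, 1 - 1e-6)
    names(lo) <- names(hi) <- c("psi", "s")
  }
  best
}

# exhaustive permutation enumerator used by the Mann-Kendall exact-p oracle
gtools_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1))
  }
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
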