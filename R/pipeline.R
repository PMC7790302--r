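#' Pipeline run configuration
#'
#' Collects the file paths, analysis flags and seeds for a full run. Every
#' stochastic step receives an explicit seed and the resolved configuration
#' is persisted alongside the outputs, so re-running an identical
#' configuration reproduces identical tables.
#'
#' @param gene_model Path to the gene annotation (GFF3 or BED12).
#' @param poison_exon_id Exon id to flag as the poison exon.
#' @param primers Optional path to the primer CSV.
#' @param depth Optional path to a samtools-depth TSV.
#' @param reads Optional path to a BED6 read file (used if `depth` is
#'   absent).
#' @param ct_table Optional path to a long-format Ct CSV.
#' @param timecourse Optional path to a time-course CSV with columns
#'   `timepoint`, `age`, `usage_percent`, `expression`.
#' @param survival Optional path to a survival CSV.
#' @param weaning Optional path to a weaning-count CSV (`genotype`, `n`).
#' @param out_dir Output directory.
#' @param wt_label,ki_label Genotype labels used to pick the two groups.
#' @param denominator,averaging Passed to [poison_usage_percent()].
#' @param fold_method,psi_ki_allele Passed to [allele_model()].
#' @param efficiency,ct_max Passed to [qpcr_inclusion()].
#' @param mapped_reads Library total stored on a loaded depth track.
#' @param n_perm Permutations for [inverse_relation()].
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(gene_model, poison_exon_id, primers = NULL,
                       depth = NULL, reads = NULL, ct_table = NULL,
                       timecourse = NULL, survival = NULL, weaning = NULL,
                       out_dir = "pexquant_out",
                       wt_label = "+/+", ki_label = "+/KI",
                       denominator = "all", averaging = "pooled",
                       fold_method = "literal", psi_ki_allele = 1,
                       efficiency = 2, ct_max = 40,
                       mapped_reads = NA_integer_, n_perm = 10000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full poison-exon quantification pipeline
#'
#' Executes every stage whose inputs are present - coverage usage, qPCR
#' inclusion and group comparison, additive-model allele fit, time-course
#' statistics, cohort statistics - writes one CSV per stage plus a
#' plain-text log into `config$out_dir`, and returns the bundle of result
#' tibbles. Missing inputs skip their stage with a warning; they do not
#' fail the run.
#'
#' @param config A [run_config()] (or path to a YAML one).
#' @return Invisibly, a list with elements `usage`, `qpcr`, `qpcr_groups`,
#'   `allele_fit`, `timecourse`, `cohort`, `log` (character vector of log
#'   lines); absent stages are `NULL`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(
    paste0("pexquant ", as.character(utils::packageVersion("pexquant"))),
    paste0("seed: ", config$seed)
  )
  note <- function(...) log <<- c(log, paste0(...))
  skip <- function(stage, why) {
    note("stage ", stage, ": skipped (", why, ")")
    warn(paste0("stage ", stage, " skipped: ", why))
    NULL
  }
  have <- function(p) !is.null(p) && file.exists(p)

  model <- load_gene_model(
    config$gene_model, config$poison_exon_id,
    primers = if (have(config$primers)) read_primer_pairs(config$primers)
  )
  note("gene model: ", model$gene_id, ", ", nrow(model$exons), " exons")

  usage <- NULL
  if (have(config$depth) || have(config$reads)) {
    track <- if (have(config$depth)) {
      load_depth(config$depth, region = model, mapped_reads = config$mapped_reads)
    } else {
      depth_from_reads(read_reads_bed(config$reads), model)
    }
    usage <- poison_usage_percent(track, model,
      denominator = config$denominator, averaging = config$averaging
    )
    readr::write_csv(usage, file.path(config$out_dir, "usage.csv"))
    note("usage: ", format(usage$usage_percent, digits = 6), " percent")
  } else {
    skip("usage", "no depth or reads input")
  }

  qpcr <- qpcr_groups <- NULL
  if (have(config$ct_table)) {
    ct <- read_ct_table(config$ct_table)
    qpcr <- qpcr_inclusion(ct,
      e2 = config$efficiency, e3 = config$efficiency, ct_max = config$ct_max
    )
    readr::write_csv(qpcr, file.path(config$out_dir, "qpcr_inclusion.csv"))
    cmp <- group_summary(qpcr, percent, genotype)
    qpcr_groups <- dplyr::bind_cols(
      tidy(cmp),
      glance(cmp)[rep(1, nrow(tidy(cmp))), ]
    )
    readr::write_csv(qpcr_groups, file.path(config$out_dir, "qpcr_groups.csv"))
    note("qpcr: ", nrow(qpcr), " samples")
  } else {
    skip("qpcr", "no Ct table")
  }

  allele_fit <- NULL
  psi_pair <- NULL
  if (!is.null(qpcr_groups)) {
    g <- qpcr_groups
    if (all(c(config$wt_label, config$ki_label) %in% g$genotype)) {
      psi_pair <- c(
        g$mean[g$genotype == config$wt_label],
        g$mean[g$genotype == config$ki_label]
      )
    }
  }
  if (!is.null(psi_pair) && psi_pair[1] > 0 && psi_pair[1] < psi_pair[2]) {
    allele_fit <- allele_model(psi_pair[1], psi_pair[2],
      psi_ki_allele = config$psi_ki_allele, fold_method = config$fold_method
    )
    readr::write_csv(allele_fit, file.path(config$out_dir, "allele_fit.csv"))
    note("allele fit: fold = ", format(allele_fit$fold_increase, digits = 4))
  } else {
    skip("allele_fit", "no usable genotype group means")
  }

  tc <- NULL
  if (have(config$timecourse)) {
    tab <- readr::read_csv(config$timecourse,
      col_types = readr::cols(), progress = FALSE
    )
    tc <- dplyr::bind_cols(
      inverse_relation(tab,
        n_perm = config$n_perm, seed = config$seed
      ) %>% rename(p_inverse = "p_perm"),
      trend_test(tab$usage_percent, tab$age) %>%
        select(S_trend = "S", p_trend = "p")
    )
    readr::write_csv(tc, file.path(config$out_dir, "timecourse_stats.csv"))
    note("timecourse: rho = ", format(tc$rho, digits = 4))
  } else {
    skip("timecourse", "no time-course table")
  }

  cohort <- NULL
  if (have(config$survival) || have(config$weaning)) {
    pieces <- list()
    if (have(config$survival)) {
      surv <- read_survival_table(config$survival)
      lr <- logrank(surv)
      km <- kaplan_meier(surv, group = genotype)
      readr::write_csv(as_tibble(km), file.path(config$out_dir, "kaplan_meier.csv"))
      pieces$logrank <- lr
      note("logrank: chisq = ", format(lr$statistic, digits = 4))
    }
    if (have(config$weaning)) {
      wn <- readr::read_csv(config$weaning,
        col_types = readr::cols(genotype = "c", n = "i"), progress = FALSE
      )
      gof <- mendelian_gof(wn$n)
      pieces$mendelian <- gof
      note("mendelian gof: chisq = ", format(gof$chisq, digits = 4))
    }
    cohort <- dplyr::bind_rows(
      if (!is.null(pieces$logrank)) {
        mutate(pieces$logrank, test = "logrank", .before = 1) %>%
          select("test", statistic = "statistic", df = "df", p = "p")
      },
      if (!is.null(pieces$mendelian)) {
        mutate(pieces$mendelian, test = "mendelian_gof", .before = 1) %>%
          select("test", statistic = "chisq", df = "df", p = "p")
      }
    )
    readr::write_csv(cohort, file.path(config$out_dir, "cohort_stats.csv"))
  } else {
    skip("cohort", "no survival or weaning input")
  }

  write_run_config(config, file.path(config$out_dir, "config.yml"))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(
    usage = usage, qpcr = qpcr, qpcr_groups = qpcr_groups,
    allele_fit = allele_fit, timecourse = tc, cohort = cohort, log = log
  ))
}

#' Generate the on-disk demonstration dataset
#'
#' Regenerates the versioned fixture bundle used by the examples and the
#' test suite: the Scn1a-like gene model in both annotation formats, the
#' primer CSV, simulated reads (BED6) and depth (samtools-depth TSV) for a
#' heterozygote brain library, a Table-1-shaped brain Ct table for both
#' genotypes (n = 4 animals each, assays amplicon2 / amplicon3 /
#' reference), a developmental time-course table, a weaned-cohort survival
#' CSV with its weaning counts, and a ready-to-run `config.yml`.
#'
#' @param dir Output directory.
#' @param seed Integer seed; the whole bundle is deterministic in it.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixtures <- function(dir, seed = 20210107L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  model <- scn1a_gene_model(with_sequence = FALSE)
  write_gene_model(model, path("gene_model.gff3"))
  write_gene_model(model, path("gene_model.bed"))
  write_primer_pairs(model$primers, path("primers.csv"))

  nmd <- nmd_params(s = 0.031)
  wt_pool <- steady_state_pool(
    genotype_spec("+/+", allele_params(1, 0.241), allele_params(1, 0.241)), nmd
  )
  ki_pool <- steady_state_pool(
    genotype_spec("+/KI", allele_params(1, 0.241), allele_params(1, 1)), nmd
  )

  sim <- simulate_reads(
    ki_pool, model,
    library_protocol("uniform", total_reads = 5e4), seed = seed
  )
  write_reads_bed(sim$reads, path("reads.bed"))
  write_depth(sim$track, path("depth.tsv"))

  qp <- qpcr_params(ct_intercept = 22.2, noise_sd = 0.15)
  ct <- dplyr::bind_rows(
    simulate_qpcr(wt_pool, qp, n = 4, genotype = "+/+", seed = seed + 1L),
    simulate_qpcr(ki_pool, qp, n = 4, genotype = "+/KI", seed = seed + 2L)
  )
  write_ct_table(ct, path("ct_table.csv"))

  tc <- simulate_timecourse(
    timecourse_plan(), model,
    library_protocol("uniform", total_reads = 1e5), seed = seed + 3L
  )
  tc_tab <- tc %>%
    mutate(usage_percent = purrr::map_dbl(
      .data$track,
      function(tr) poison_usage_percent(tr, model)$usage_percent
    )) %>%
    select("timepoint", "age", "usage_percent", "expression")
  readr::write_csv(tc_tab, path("timecourse.csv"))

  cohort <- simulate_cohort(cohort_plan(), seed = seed + 4L)
  write_survival_table(cohort$survival, path("survival.csv"))
  readr::write_csv(cohort$weaning, path("weaning.csv"))

  cfg <- run_config(
    gene_model = path("gene_model.gff3"), poison_exon_id = "ex20N",
    primers = path("primers.csv"), depth = path("depth.tsv"),
    ct_table = path("ct_table.csv"), timecourse = path("timecourse.csv"),
    survival = path("survival.csv"), weaning = path("weaning.csv"),
    out_dir = path("results"), mapped_reads = sim$mapped_reads,
    seed = seed
  )
  write_run_config(cfg, path("config.yml"))
  invisible(list(
    gene_model = path("gene_model.gff3"), gene_model_bed = path("gene_model.bed"),
    primers = path("primers.csv"), reads = path("reads.bed"),
    depth = path("depth.tsv"), ct_table = path("ct_table.csv"),
    timecourse = path("timecourse.csv"), survival = path("survival.csv"),
    weaning = path("weaning.csv"), config = path("config.yml")
  ))
}
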