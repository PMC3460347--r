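# Study configuration and the simulate -> erp -> rvip -> stats orchestration.

#' Default study configuration
#'
#' Nested list of every tunable pipeline parameter, YAML-serializable and
#' round-trip identical. Effect-model parameters are the [effect_model()]
#' defaults and are reconstructed through it on use.
#'
#' @param seed Master seed recorded in the configuration.
#' @return A list of class `study_config`.
#' @export
default_study_config <- function(seed = 1L) {
  structure(list(
    paradigm = list(duration_min = 12, rate_per_min = 110,
                    targets_per_min = 10, min_separation = 5,
                    n_tones = 1200, deviant_fraction = 0.10,
                    soa_range_ms = c(445, 645), n_blocks = 3),
    study = list(n_per_group = 12),
    pipeline = list(pre_ms = 50, total_ms = 500, threshold_uv = 100,
                    mmn_window_ms = c(80, 220), rvip_window_ms = c(100, 1000),
                    min_deviants = 30),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Validate a study configuration
#'
#' Checks the ranges and divisibility rules declared by the generator and
#' pipeline modules; stops with a message listing every offending key.
#'
#' @param config A `study_config` list.
#' @return The config, invisibly, if valid.
#' @export
validate_study_config <- function(config) {
  bad <- character(0)
  p <- config$paradigm
  if (is.null(p)) bad <- c(bad, "paradigm")
  else {
    if (p$duration_min < 0 || p$duration_min != round(p$duration_min)) {
      bad <- c(bad, "paradigm.duration_min")
    }
    if (p$duration_min > 0) {
      if ((p$duration_min * p$rate_per_min) %% p$n_blocks != 0) {
        bad <- c(bad, "paradigm.rate_per_min")
      }
      if (p$n_tones %% p$n_blocks != 0) {
        bad <- c(bad, "paradigm.n_tones")
      } else {
        kd <- p$deviant_fraction * p$n_tones / p$n_blocks
        if (abs(kd - round(kd)) > 1e-9) bad <- c(bad, "paradigm.deviant_fraction")
      }
    }
    if (p$soa_range_ms[1] > p$soa_range_ms[2] || p$soa_range_ms[1] < 50) {
      bad <- c(bad, "paradigm.soa_range_ms")
    }
  }
  s <- config$pipeline
  if (!is.null(s)) {
    if (s$pre_ms < 4 || s$pre_ms >= s$total_ms) bad <- c(bad, "pipeline.pre_ms")
    if (s$threshold_uv <= 0) bad <- c(bad, "pipeline.threshold_uv")
    if (s$mmn_window_ms[1] >= s$mmn_window_ms[2]) {
      bad <- c(bad, "pipeline.mmn_window_ms")
    }
  }
  if (config$study$n_per_group < 2) bad <- c(bad, "study.n_per_group")
  if (length(bad)) {
    stop("invalid configuration key(s): ", paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' Read / write a study configuration as YAML
#'
#' @param config A `study_config`.
#' @param path YAML file path.
#' @return `save_study_config` returns the path; `load_study_config` the
#'   validated config.
#' @export
save_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_study_config
#' @export
load_study_config <- function(path) {
  config <- structure(yaml::read_yaml(path), class = "study_config")
  # yaml scalarizes length-2 vectors fine; coerce numeric vectors back
  for (k in c("soa_range_ms")) {
    config$paradigm[[k]] <- as.numeric(config$paradigm[[k]])
  }
  for (k in c("mmn_window_ms", "rvip_window_ms")) {
    config$pipeline[[k]] <- as.numeric(config$pipeline[[k]])
  }
  validate_study_config(config)
  config
}

schedule_from_config <- function(p) {
  digits <- generate_digit_stream(p$duration_min, p$rate_per_min,
                                  p$targets_per_min, p$min_separation,
                                  p$soa_range_ms)
  tones <- generate_tone_stream(p$n_tones, p$deviant_fraction,
                                p$soa_range_ms, p$n_blocks)
  interleave(tones, digits, soa_range_ms = p$soa_range_ms)
}

#' Run the simulate / erp / rvip / stats pipeline to disk
#'
#' Orchestrates the full study: `simulate` writes one events TSV, EEG
#' CSV+JSON, and press TSV per subject x session plus a manifest; `erp`
#' reads the recordings back and writes the MMN measures table; `rvip`
#' scores the presses into block metrics; `stats` fits the split-plot ANOVA
#' for each measure and writes ANOVA, pairwise-family, and correlation
#' tables. Deterministic given (config, seed). Later stages require the
#' earlier stages' outputs on disk.
#'
#' @param config A validated `study_config`.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "erp", "rvip", "stats")`.
#' @param seed Overrides `config$seed` when given.
#' @param effects An `effect_model` (defaults used otherwise).
#' @return Named list of written paths, invisibly.
#' @export
run_pipeline <- function(config = default_study_config(), out_dir,
                         stages = c("simulate", "erp", "rvip", "stats"),
                         seed = NULL, effects = effect_model()) {
  validate_study_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  paths <- list()
  manifest_path <- file.path(out_dir, "manifest.tsv")
  pp <- config$pipeline

  if ("simulate" %in% stages) {
    writer <- function(rec) {
      prefix <- file.path(out_dir, sprintf("sub%02d_ses%d", rec$subject,
                                           rec$order_position))
      write_events_tsv(rec$schedule, paste0(prefix, "_events.tsv"))
      write_recording(rec$recording, prefix)
      write_presses_tsv(rec$presses, paste0(prefix, "_presses.tsv"))
      prefix
    }
    sim <- simulate_study(config$study$n_per_group, effects, seed = seed,
                          handler = writer, paradigm = config$paradigm)
    manifest <- sim$manifest
    manifest$prefix <- basename(unlist(sim$records))
    write_tsv(manifest, manifest_path)
    paths$manifest <- manifest_path
  }

  if (any(c("erp", "rvip", "stats") %in% stages) &&
      !file.exists(manifest_path)) {
    stop("stage dependency error: run the 'simulate' stage first (no ",
         manifest_path, ")")
  }
  manifest <- if (file.exists(manifest_path)) read_tsv(manifest_path)

  if ("erp" %in% stages) {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      prefix <- file.path(out_dir, manifest$prefix[i])
      rec <- read_recording(prefix)
      mm <- measure_recording(rec, threshold_uv = pp$threshold_uv,
                              window_ms = pp$mmn_window_ms,
                              pre_ms = pp$pre_ms, total_ms = pp$total_ms,
                              min_deviants = pp$min_deviants)
      cbind(manifest[i, c("subject", "group", "gum", "drug")], mm,
            row.names = NULL)
    })
    paths$mmn_measures <- file.path(out_dir, "mmn_measures.tsv")
    write_tsv(do.call(rbind, rows), paths$mmn_measures)
  }

  if ("rvip" %in% stages) {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      prefix <- file.path(out_dir, manifest$prefix[i])
      schedule <- read_events_tsv(paste0(prefix, "_events.tsv"),
                                  config$paradigm$duration_min)
      presses <- read_presses_tsv(paste0(prefix, "_presses.tsv"))
      rv <- block_metrics(schedule$digit_stream, presses,
                          window_ms = pp$rvip_window_ms)
      cbind(manifest[i, c("subject", "group", "gum", "drug")], rv,
            row.names = NULL)
    })
    paths$rvip_metrics <- file.path(out_dir, "rvip_metrics.tsv")
    write_tsv(do.call(rbind, rows), paths$rvip_metrics)
  }

  if ("stats" %in% stages) {
    mmn_path <- file.path(out_dir, "mmn_measures.tsv")
    rvip_path <- file.path(out_dir, "rvip_metrics.tsv")
    if (!file.exists(mmn_path) || !file.exists(rvip_path)) {
      stop("stage dependency error: run the 'erp' and 'rvip' stages first")
    }
    mmn <- read_tsv(mmn_path)
    rvip <- read_tsv(rvip_path)
    dvs <- list(mmn_amplitude = list(mmn, "amplitude_uv"),
                mmn_latency = list(mmn, "latency_ms"),
                pct_hits = list(rvip, "pct_hits"),
                pct_fa = list(rvip, "pct_fa"),
                mean_rt = list(rvip, "mean_rt_ms"),
                dprime = list(rvip, "dprime"))
    anova_rows <- lapply(names(dvs), function(nm) {
      fit <- split_plot_anova(dvs[[nm]][[1]], dv = dvs[[nm]][[2]])
      cbind(measure = nm, fit$table, row.names = NULL)
    })
    paths$anova <- file.path(out_dir, "anova.tsv")
    write_tsv(do.call(rbind, anova_rows), paths$anova)

    # placebo-session correlation between MMN amplitude and d-prime,
    # collapsed across groups and blocks
    pl_m <- mmn[mmn$gum == "PG" & mmn$drug == "PI", ]
    pl_d <- rvip[rvip$gum == "PG" & rvip$drug == "PI", ]
    m_by_s <- tapply(pl_m$amplitude_uv, pl_m$subject, mean)
    d_by_s <- tapply(pl_d$dprime, pl_d$subject, mean)
    subs <- intersect(names(m_by_s), names(d_by_s))
    paths$correlation <- file.path(out_dir, "correlation.tsv")
    write_tsv(cbind(analysis = "placebo_mmn_vs_dprime",
                    mmn_dprime_correlation(m_by_s[subs], d_by_s[subs])),
              paths$correlation)
  }
  invisible(paths)
}

#' Signed contrasts for the built-in effect pattern
#'
#' Computes, from measured study tables, the three signed quantities the
#' default effect model builds in: (1) the ketamine-induced MMN amplitude
#' reduction in the H-HD group under placebo gum (mean amplitude PG-KI minus
#' PG-PI; positive = reduced negativity); (2) its blockade by nicotine (the
#' PG ketamine effect minus the NG ketamine effect in H-HD; positive =
#' blocked); (3) the nicotine hit-rate improvement under placebo infusion
#' (mean %hits NG-PI minus PG-PI; positive = improved).
#'
#' @param mmn,rvip Measured tables from [simulate_measured_study()] (columns
#'   `group`, `gum`, `drug`, `amplitude_uv` / `pct_hits`).
#' @return Named numeric vector `c(ki_reduction, ng_blockade, ng_hits)`.
#' @export
effect_pattern_contrasts <- function(mmn, rvip) {
  amp <- function(gum, drug) {
    mean(mmn$amplitude_uv[mmn$group == "H-HD" & mmn$gum == gum &
                            mmn$drug == drug])
  }
  hits <- function(gum) {
    mean(rvip$pct_hits[rvip$gum == gum & rvip$drug == "PI"])
  }
  ki_reduction <- amp("PG", "KI") - amp("PG", "PI")
  ng_blockade <- ki_reduction - (amp("NG", "KI") - amp("NG", "PI"))
  c(ki_reduction = ki_reduction, ng_blockade = ng_blockade,
    ng_hits = hits("NG") - hits("PG"))
}
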