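# End-to-end pipeline: simulate -> QC -> fit -> metrics -> report, driven
# by a single (YAML-able) config and fully determined by its seed.

#' Default pipeline configuration
#'
#' Blocks: `task` (repeats), `norms` (offset, clip), `simulate`
#' (cohort size, domains, injected rule-breakers, optionally
#' `w_norm_fixed` to pin the conformity weight, e.g. 0 for a no-conformity
#' control run), `fit` (engine, quadrature nodes), `analyze` (parametric
#' draws, confidence level).
#'
#' @param ... Named top-level overrides merged over the defaults.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    task = list(repeats = 4L),
    norms = list(offset = 0.20, clip = c(0.05, 0.95)),
    simulate = list(
      n_per_cell = 12L,
      domains = c("moral", "monetary"),
      exclusion_injection = list(n_constant = 1L, n_failed_comprehension = 1L,
                                 n_failed_attention = 0L),
      w_norm_fixed = NULL
    ),
    fit = list(engine = "glmer", nagq = 15L),
    analyze = list(n_draws = 1000L, level = 0.95)
  )
  utils::modifyList(cfg, list(...))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path.",
                             call. = FALSE)
  utils::modifyList(default_config(), config)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Model-based per-value gamble probabilities of one cell (used for the
# uncertainty-alignment metric).
model_phase_curve <- function(fit, cell) {
  values <- cell$gamble_value %||% value_grid("own")
  X <- cell_model_matrix(fit, c(cell, list(gamble_value = values)))
  gh <- gh_normal(15)
  eta <- drop(X %*% fit$coef)
  p <- 0
  for (k in seq_along(gh$z)) {
    p <- p + gh$w[k] * stats::plogis(eta + fit$re_sd * gh$z[k])
  }
  tibble::tibble(gamble_value = values, p = p)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, deterministically from the config seed: cohort simulation,
#' QC exclusions, the day-0 and persistence mixed-logit fits, conformity
#' influence and persistence per design cell (with the adjusted contrast
#' family per domain x frame), the entropy comparison, the
#' uncertainty-alignment metric and the awareness-conformity correlation.
#' Optionally writes a report bundle (CSV tables and a manifest with the
#' seed, package version, config echo and data hashes).
#'
#' @param config Configuration list or YAML file path (see
#'   [default_config()]).
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `conformity_report` with elements `cohort`,
#'   `qc`, `fit_d0`, `fit_d3`, `influence`, `persistence`, `contrasts`,
#'   `entropy`, `alignment`, `awareness`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- read_config(config)
  seed <- as.integer(cfg$seed)

  stage_log("simulate", "cohort of %d participants/cell, domains: %s, seed %d",
            cfg$simulate$n_per_cell,
            paste(cfg$simulate$domains, collapse = "/"), seed)
  design <- default_design()
  design <- design[design$domain %in% cfg$simulate$domains, ]
  priors <- default_param_priors()
  if (!is.null(cfg$simulate$w_norm_fixed)) {
    w0 <- as.numeric(cfg$simulate$w_norm_fixed)
    priors$w_norm <- function(n) rep(w0, n)
  }
  sim <- simulate_cohort(
    n_per_cell = cfg$simulate$n_per_cell,
    design = design,
    param_priors = priors,
    exclusion_injection = cfg$simulate$exclusion_injection,
    seed = seed,
    repeats = cfg$task$repeats,
    offset = cfg$norms$offset,
    clip = as.numeric(cfg$norms$clip)
  )

  stage_log("qc", "applying exclusion rules")
  qc <- apply_exclusions(sim$trials, sim$comprehension_flags,
                         sim$attention_flags)
  stage_log("qc", "%d of %d participants retained",
            qc$report$n_retained, qc$report$n_input)

  fit_one <- function(trials) {
    if (cfg$fit$engine == "glmer") {
      fit_mixed_logit(trials, nagq = cfg$fit$nagq)
    } else {
      fit_pooled_logit(trials)
    }
  }
  stage_log("fit", "day-0 model (%s)", cfg$fit$engine)
  d0_trials <- qc$trials[qc$trials$phase %in% c("baseline", "ownD0"), ]
  fit_d0 <- fit_one(d0_trials)
  stage_log("fit", "persistence model (%s)", cfg$fit$engine)
  d3_trials <- qc$trials[qc$trials$phase %in% c("baseline", "ownD3"), ]
  fit_d3 <- if (any(d3_trials$phase == "ownD3")) fit_one(d3_trials) else NULL

  stage_log("analyze", "influence, persistence and contrasts per cell")
  nd <- cfg$analyze$n_draws
  lv <- cfg$analyze$level
  cells <- design
  has_domain <- "domain" %in% names(fit_d0$xlevels)
  cond_of <- function(row) {
    cond <- list(frame = row$frame, norm_type = row$norm_type)
    if (has_domain) cond$domain <- row$domain
    cond
  }
  influence <- persistence_est <- alignment <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cond <- cond_of(cells[i, ])
    influence[[i]] <- influence_curve(fit_d0, cond, n_draws = nd, level = lv,
                                      seed = derive_seed(seed, c(3, i)))
    if (!is.null(fit_d3)) {
      persistence_est[[i]] <- persistence(fit_d3, cond, n_draws = nd,
                                          level = lv,
                                          seed = derive_seed(seed, c(4, i)))
    }
    alignment[[i]] <- peak_influence_alignment(
      influence[[i]],
      model_phase_curve(fit_d0, c(cond, list(phase = "baseline")))
    )
  }
  names(influence) <- names(alignment) <-
    apply(cells, 1, paste, collapse = ".")
  if (!is.null(fit_d3)) names(persistence_est) <- names(influence)

  # adjusted contrast family: ownD0 vs baseline in every cell, per domain
  contrasts <- lapply(split(seq_len(nrow(cells)), cells$domain), function(ix) {
    fam <- lapply(ix, function(i) {
      cond <- cond_of(cells[i, ])
      list(a = c(cond, list(phase = "ownD0")),
           b = c(cond, list(phase = "baseline")))
    })
    names(fam) <- paste(cells$frame[ix], cells$norm_type[ix], sep = ".")
    contrast_cells(fit_d0, fam, n_draws = max(2000, nd), level = lv,
                   seed = derive_seed(seed, 5))
  })

  stage_log("analyze", "entropy and awareness metrics")
  entropy <- entropy_phase_comparison(qc$trials)
  conf <- participant_conformity(qc$trials)
  aware <- sim$agents$awareness[match(conf$participant_id,
                                      sim$agents$participant_id)]
  awareness <- awareness_conformity_correlation(aware, conf$conformity)

  report <- structure(list(
    cohort = sim, qc = qc$report, trials = qc$trials,
    fit_d0 = fit_d0, fit_d3 = fit_d3,
    influence = influence, persistence = persistence_est,
    contrasts = contrasts, entropy = entropy, alignment = alignment,
    awareness = awareness, config = cfg
  ), class = "conformity_report")

  if (!is.null(out_dir)) {
    stage_log("report", "writing bundle to %s", out_dir)
    write_report_bundle(report, out_dir)
  }
  report
}

write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials_path <- file.path(out_dir, "trials.csv")
  write_trials(report$trials, trials_path)
  readr::write_csv(report$cohort$agents, file.path(out_dir, "agents.csv"),
                   progress = FALSE)
  readr::write_csv(report$qc$flags, file.path(out_dir, "qc_flags.csv"),
                   progress = FALSE)
  infl <- dplyr::bind_rows(lapply(names(report$influence), function(nm) {
    x <- report$influence[[nm]]
    tibble::tibble(cell = nm, marginal_delta = x$marginal_delta,
                   ci_low = x$ci_low, ci_high = x$ci_high,
                   abs_magnitude = x$abs_magnitude)
  }))
  readr::write_csv(infl, file.path(out_dir, "influence.csv"), progress = FALSE)
  readr::write_csv(dplyr::bind_rows(report$contrasts, .id = "domain"),
                   file.path(out_dir, "contrasts.csv"), progress = FALSE)
  readr::write_csv(tidy_fit(report$fit_d0), file.path(out_dir, "fit_d0.csv"),
                   progress = FALSE)
  manifest <- list(
    package = "riskconform",
    version = as.character(utils::packageVersion("riskconform")),
    seed = report$config$seed,
    config = report$config,
    hashes = as.list(tools::md5sum(trials_path))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.conformity_report <- function(x, ...) {
  cat("Conformity analysis report\n")
  print(x$qc)
  cat("Marginal influence (ownD0 vs baseline):\n")
  for (nm in names(x$influence)) {
    cat(sprintf("  %-28s %+.3f [%.3f, %.3f]\n", nm,
                x$influence[[nm]]$marginal_delta,
                x$influence[[nm]]$ci_low, x$influence[[nm]]$ci_high))
  }
  if (!x$entropy$degenerate) {
    cat(sprintf("Entropy baseline vs transfer: Wilcoxon p = %.3g\n",
                x$entropy$test$p_value))
  }
  cat(sprintf("Awareness-conformity: r(%d) = %.3f, p = %.3g\n",
              x$awareness$df, x$awareness$r, x$awareness$p))
  invisible(x)
}
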