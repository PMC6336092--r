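#' Score a full assessment
#'
#' Runs the whole scoring pipeline for every (site, service) pair declared
#' in the configuration: pooled outlier screening per service, reference
#' point selection, present-status normalization, the five-year trend with
#' confidence interval, factor-by-factor pressure-resilience scoring, the
#' near-term future-status projection, and the service and sustainability
#' scores. No pair is silently dropped: cells that cannot be computed are
#' reported as `NA` with explanatory flags.
#'
#' @param config A [cei_config()] object.
#' @param indicators Tidy indicator table (`site_id`, `service_id`, `year`,
#'   `value`), e.g. from [read_indicator_series()].
#' @param factor_obs Optional factor observation table (`site_id`,
#'   `service_id`, `factor_id`, `year`, `value`, `state`), e.g. from
#'   [read_factor_observations()].
#' @return A `cei_assessment` object: a list with
#'   \describe{
#'     \item{scores}{one row per (site, service) with `X`, `x`, `slope`,
#'       `se`, `T`, `T_lower`, `T_upper`, `n_points`, `PR`, `x_F_raw`,
#'       `x_F`, `I`, `S` and a `flags` string (`;`-separated condition
#'       codes).}
#'     \item{reference_points}{per service: `X_R` with source site/year and
#'       the pooled window.}
#'     \item{factor_scores}{one row per (site, service, factor) with the
#'       score and its basis.}
#'     \item{screening}{every pooled observation with its retained/excluded
#'       status.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
score_assessment <- function(config, indicators, factor_obs = NULL) {
  stopifnot(inherits(config, "cei_config"))
  indicators <- .check_indicator_data(as_tibble(indicators), config)
  if (!is.null(factor_obs)) {
    factor_obs <- as_tibble(factor_obs)
    factor_obs <- .fill_column(factor_obs, "value", NA_real_)
    factor_obs <- .fill_column(factor_obs, "state", NA_character_)
    .check_factor_data(factor_obs, config)
  }

  parts <- lapply(seq_len(nrow(config$services)), function(i) {
    .assess_service(config, config$services[i, ], indicators, factor_obs)
  })

  structure(
    list(
      scores = dplyr::bind_rows(lapply(parts, `[[`, "scores")),
      reference_points = dplyr::bind_rows(lapply(parts, `[[`, "reference")),
      factor_scores = dplyr::bind_rows(lapply(parts, `[[`, "factor_scores")),
      screening = dplyr::bind_rows(lapply(parts, `[[`, "screening")),
      config = config
    ),
    class = "cei_assessment"
  )
}

#' @export
print.cei_assessment <- function(x, ...) {
  cat(sprintf("<cei_assessment> %d sites x %d services, evaluation year %d\n",
              nrow(x$config$sites), nrow(x$config$services),
              x$config$evaluation_year))
  print(format_score_matrix(x))
  invisible(x)
}

# Scores one service across all sites. Internal; explain_cell() and the
# report writers consume the tables this produces.
.assess_service <- function(config, sdef, indicators, factor_obs) {
  sid <- sdef$service_id
  yrs <- .window_years(config)
  ind_s <- indicators[indicators$service_id == sid & indicators$year %in% yrs, ,
                      drop = FALSE]
  scr <- screen_outliers(ind_s, k = config$outlier_k)
  ref <- reference_point(scr$retained, sid,
                         fixed = config$reference_points[[sid]])
  fdefs <- config$factors[config$factors$service_id == sid, , drop = FALSE]
  fobs_s <- if (is.null(factor_obs)) NULL else {
    factor_obs[factor_obs$service_id == sid, , drop = FALSE]
  }

  screening <- tibble(
    service_id = sid,
    site_id = ind_s$site_id,
    year = ind_s$year,
    value = ind_s$value,
    excluded = seq_len(nrow(ind_s)) %in%
      which(paste(ind_s$site_id, ind_s$year) %in%
              paste(scr$excluded$site_id, scr$excluded$year))
  )

  rows <- list()
  fscores <- list()
  for (st in config$sites$site_id) {
    res <- .score_site_service(config, sdef, st, scr, ref, fdefs, fobs_s)
    res$score_row$flags <- paste(unique(c(scr$flags, res$flags)),
                                 collapse = ";")
    rows[[st]] <- res$score_row
    fscores[[st]] <- res$factor_scores
  }

  list(
    scores = dplyr::bind_rows(rows),
    reference = tibble(
      service_id = sid, X_R = ref$X_R,
      source_site = ref$source_site, source_year = ref$source_year,
      window_first = min(yrs), window_last = max(yrs), fixed = ref$fixed
    ),
    factor_scores = dplyr::bind_rows(fscores),
    screening = screening
  )
}

.score_site_service <- function(config, sdef, site_id, scr, ref, fdefs, fobs_s) {
  sid <- sdef$service_id
  flags <- character()

  pooled <- rbind(scr$retained, scr$excluded)
  site_rows <- pooled[pooled$site_id == site_id, , drop = FALSE]
  eval_row <- site_rows[site_rows$year == config$evaluation_year, , drop = FALSE]
  X <- if (nrow(eval_row) > 0) eval_row$value[1] else NA_real_
  if (is.na(X)) {
    flags <- c(flags, "NO_DATA")
  } else if (any(scr$excluded$site_id == site_id &
                 scr$excluded$year == config$evaluation_year)) {
    flags <- c(flags, "OUTLIER_EVAL_YEAR")
  }
  x <- if (is.na(X)) NA_real_ else present_status(X, ref)

  retained_site <- scr$retained[scr$retained$site_id == site_id, , drop = FALSE]
  tr <- fit_trend(retained_site$year, retained_site$value / ref$X_R,
                  min_points = config$min_trend_points)
  flags <- c(flags, tr$flags)

  fs <- .score_factors(config, site_id, sid, fdefs, fobs_s)
  if (nrow(fs) > 0 && any(fs$basis == "missing" & fs$unknown)) {
    flags <- c(flags, "FACTOR_UNKNOWN")
  }
  PR <- if (nrow(fs) == 0) NA_real_ else {
    aggregate_pr(fs$score, weights = fs$weight)
  }
  pr_used <- PR
  if (is.na(PR)) {
    flags <- c(flags, "NO_PR", "PR_DEFAULTED")
    pr_used <- 0
  }

  if (is.na(x)) {
    x_F_raw <- x_F <- I <- S <- NA_real_
  } else {
    x_F_raw <- future_status(x, tr$T, pr_used, config$beta, clamp = FALSE)
    x_F <- min(1, x_F_raw)
    if (x_F_raw > 1 + 1e-12) flags <- c(flags, "CLAMPED_FUTURE")
    I <- service_score(x, x_F, config$report_scale)
    S <- sustainability(x, x_F)
    if (x == 0) flags <- c(flags, "X_ZERO")
    # Algebraic identity: absent clamping, S reduces to the weighted sum of
    # trend and PR. Guards against drift between the composed stages.
    if (x > 0 && x_F_raw <= 1 + 1e-12) {
      expected <- config$beta * tr$T + (1 - config$beta) * pr_used
      stopifnot(abs(S - expected) <= 1e-9)
    }
  }

  list(
    score_row = tibble(
      site_id = site_id, service_id = sid,
      X = X, x = x,
      slope = tr$slope, se = tr$se, T = tr$T,
      T_lower = tr$T_lower, T_upper = tr$T_upper, n_points = tr$n_points,
      PR = PR, x_F_raw = x_F_raw, x_F = x_F, I = I, S = S,
      flags = NA_character_
    ),
    factor_scores = fs,
    flags = flags
  )
}

# Scores every declared factor of a service for one site. Returns one row
# per factor with score, basis, and whether an unknown state was seen.
.score_factors <- function(config, site_id, service_id, fdefs, fobs_s) {
  empty <- tibble(site_id = character(), service_id = character(),
                  factor_id = character(), score = numeric(),
                  basis = character(), weight = numeric(),
                  unknown = logical())
  if (nrow(fdefs) == 0) return(empty)
  yrs <- if (config$pr_years == "evaluation") {
    config$evaluation_year
  } else {
    .window_years(config)
  }
  rows <- lapply(seq_len(nrow(fdefs)), function(i) {
    f <- fdefs[i, ]
    obs <- if (is.null(fobs_s)) fdefs[0, ] else {
      fobs_s[fobs_s$factor_id == f$factor_id &
               fobs_s$site_id == site_id &
               fobs_s$year %in% yrs, , drop = FALSE]
    }
    unknown <- FALSE
    if (nrow(obs) == 0) {
      score <- NA_real_
      basis <- "missing"
    } else if (f$kind == "quantitative") {
      yearly <- quantitative_factor_score(obs$value, f)
      score <- if (all(is.na(yearly))) NA_real_ else mean(yearly, na.rm = TRUE)
      basis <- if (is.na(score)) "missing" else "quantitative"
    } else {
      yearly <- qualitative_factor_score(obs$state, f)
      unknown <- any(obs$state == "unknown")
      score <- if (all(is.na(yearly))) NA_real_ else mean(yearly, na.rm = TRUE)
      basis <- if (is.na(score)) "missing" else "qualitative"
    }
    tibble(site_id = site_id, service_id = service_id,
           factor_id = f$factor_id, score = score, basis = basis,
           weight = f$weight, unknown = unknown)
  })
  dplyr::bind_rows(rows)
}

#' Format the score matrix
#'
#' Lays the assessment out as the conventional report matrix: one row per
#' service, one column per site, each cell `"I/S%"` with the service score
#' to one decimal place and the sustainability score as a signed whole
#' percent; a dash marks quantities that could not be computed (e.g.
#' `"0.0/-"` where present status is zero, `"-/-"` where the service does
#' not apply at the site).
#'
#' @param assessment A `cei_assessment` (or its `scores` tibble plus a
#'   `config`).
#' @return A tibble with `service_id` and one character column per site.
#' @export
format_score_matrix <- function(assessment) {
  scores <- assessment$scores
  sites <- assessment$config$sites$site_id
  services <- assessment$config$services$service_id
  cells <- scores
  cells$cell <- .format_cell(scores$I, scores$S)
  wide <- tidyr::pivot_wider(
    cells[, c("service_id", "site_id", "cell")],
    names_from = "site_id", values_from = "cell"
  )
  wide <- wide[match(services, wide$service_id), c("service_id", sites)]
  wide
}

.format_cell <- function(I, S) {
  fmt_s <- function(s) {
    if (is.na(s)) return("-")
    pct <- round(100 * s)
    if (pct > 0) sprintf("+%d%%", pct)
    else if (pct < 0) sprintf("%d%%", pct)
    else "0%"
  }
  mapply(function(i, s) {
    if (is.na(i)) "-/-" else sprintf("%.1f/%s", i, fmt_s(s))
  }, I, S, USE.NAMES = FALSE)
}

#' Parse a printed score matrix back to tidy form
#'
#' Inverse of [format_score_matrix()] at printed precision: service scores
#' are recovered to one decimal place and sustainability scores to a whole
#' percent; dashes become `NA`.
#'
#' @param path A TSV written from [format_score_matrix()].
#' @return A tibble with `service_id`, `site_id`, `I`, `S`.
#' @export
parse_score_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  long <- tidyr::pivot_longer(wide, -"service_id",
                              names_to = "site_id", values_to = "cell")
  parts <- strsplit(long$cell, "/", fixed = TRUE)
  long$I <- vapply(parts, function(p) {
    if (p[1] == "-") NA_real_ else as.numeric(p[1])
  }, numeric(1))
  long$S <- vapply(parts, function(p) {
    if (length(p) < 2 || p[2] == "-") NA_real_ else {
      as.numeric(sub("%", "", p[2])) / 100
    }
  }, numeric(1))
  long[, c("service_id", "site_id", "I", "S")]
}

#' Countermeasure digest
#'
#' For each site, lists the services whose sustainability score is
#' negative (the service is expected to decay under present conditions)
#' together with the environmental factors scoring below zero -- the
#' factors where countermeasures would be effective.
#'
#' @param assessment A `cei_assessment`.
#' @return A tibble with `site_id`, `service_id`, `S`, `factor_id`,
#'   `factor_score`; factor columns are `NA` for a decaying service with
#'   no negative factor on record.
#' @export
countermeasure_digest <- function(assessment) {
  scores <- assessment$scores
  declining <- scores[!is.na(scores$S) & scores$S < 0, , drop = FALSE]
  if (nrow(declining) == 0) {
    return(tibble(site_id = character(), service_id = character(),
                  S = numeric(), factor_id = character(),
                  factor_score = numeric()))
  }
  rows <- lapply(seq_len(nrow(declining)), function(i) {
    d <- declining[i, ]
    fs <- assessment$factor_scores
    fs <- fs[fs$site_id == d$site_id & fs$service_id == d$service_id, ,
             drop = FALSE]
    bad_ids <- factor_diagnostics(fs)
    if (length(bad_ids) == 0) {
      tibble(site_id = d$site_id, service_id = d$service_id, S = d$S,
             factor_id = NA_character_, factor_score = NA_real_)
    } else {
      tibble(site_id = d$site_id, service_id = d$service_id, S = d$S,
             factor_id = bad_ids,
             factor_score = fs$score[match(bad_ids, fs$factor_id)])
    }
  })
  dplyr::bind_rows(rows)
}

#' Run an assessment from files and write all report artifacts
#'
#' Reads the configuration and data, scores the assessment, and writes the
#' full report set to `out_dir`:
#' \describe{
#'   \item{`score_matrix.tsv`}{the service-by-site `"I/S%"` matrix.}
#'   \item{`scores.csv`}{the tidy long form of every computed quantity and
#'     flag.}
#'   \item{`reference_points.csv`}{per-service reference points with
#'     provenance.}
#'   \item{`trend_ci.csv`}{trend scores with confidence bounds.}
#'   \item{`countermeasures.csv`}{decaying services and their negative
#'     factors.}
#'   \item{`flags.csv`}{structured log of every flag raised (one row per
#'     site, service, flag).}
#'   \item{`radar/<site>__<service>.csv`}{per-cell factor scores for radar
#'     charting.}
#' }
#'
#' @param config_path Path to the YAML/JSON configuration.
#' @param data_dir Directory containing `indicators.csv` and (optionally)
#'   `factor_observations.csv`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `assessment` object and the `paths`
#'   of the written artifacts.
#' @export
run_assessment <- function(config_path, data_dir, out_dir) {
  config <- read_cei_config(config_path)
  ind_path <- file.path(data_dir, "indicators.csv")
  if (!file.exists(ind_path)) {
    abort(sprintf("indicator file not found: %s", ind_path),
          class = "cei_data_error")
  }
  indicators <- read_indicator_series(ind_path)
  fob_path <- file.path(data_dir, "factor_observations.csv")
  factor_obs <- if (file.exists(fob_path)) read_factor_observations(fob_path)

  assessment <- score_assessment(config, indicators, factor_obs)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "radar"), showWarnings = FALSE)
  paths <- list(
    score_matrix = file.path(out_dir, "score_matrix.tsv"),
    scores = file.path(out_dir, "scores.csv"),
    reference_points = file.path(out_dir, "reference_points.csv"),
    trend_ci = file.path(out_dir, "trend_ci.csv"),
    countermeasures = file.path(out_dir, "countermeasures.csv"),
    flags = file.path(out_dir, "flags.csv")
  )

  readr::write_tsv(format_score_matrix(assessment), paths$score_matrix,
                   progress = FALSE)
  readr::write_csv(assessment$scores, paths$scores, progress = FALSE)
  readr::write_csv(assessment$reference_points, paths$reference_points,
                   progress = FALSE)
  trend_tbl <- assessment$scores[, c("site_id", "service_id", "T", "T_lower",
                                     "T_upper", "n_points", "flags")]
  readr::write_csv(trend_tbl, paths$trend_ci, progress = FALSE)
  readr::write_csv(countermeasure_digest(assessment), paths$countermeasures,
                   progress = FALSE)

  flag_rows <- assessment$scores[, c("site_id", "service_id", "flags")]
  flag_rows <- flag_rows[!is.na(flag_rows$flags) & flag_rows$flags != "", ,
                         drop = FALSE]
  flag_long <- tidyr::separate_rows(flag_rows, "flags", sep = ";")
  names(flag_long)[names(flag_long) == "flags"] <- "flag"
  readr::write_csv(flag_long, paths$flags, progress = FALSE)

  fs <- assessment$factor_scores
  radar_paths <- character()
  if (nrow(fs) > 0) {
    keys <- unique(fs[, c("site_id", "service_id")])
    for (i in seq_len(nrow(keys))) {
      sub <- fs[fs$site_id == keys$site_id[i] &
                  fs$service_id == keys$service_id[i],
                c("factor_id", "score", "basis")]
      p <- file.path(out_dir, "radar",
                     sprintf("%s__%s.csv", keys$site_id[i], keys$service_id[i]))
      readr::write_csv(sub, p, progress = FALSE)
      radar_paths <- c(radar_paths, p)
    }
  }
  paths$radar <- radar_paths

  invisible(list(assessment = assessment, paths = paths))
}

#' Explain one (site, service) cell
#'
#' Emits the full audit trail behind one cell of the score matrix: the
#' pooled window with retained and excluded observations, the reference
#' point and its provenance, the normalized present status, the trend
#' slope with standard error and confidence interval, every factor score,
#' the PR aggregate (noting when it was not evaluated and defaulted to 0),
#' the raw and clamped future status, and the service and sustainability
#' scores, along with every flag raised.
#'
#' @param assessment A `cei_assessment`.
#' @param site_id,service_id The cell to explain.
#' @param quiet Suppress printing and just return the report lines.
#' @return Invisibly (or visibly with `quiet = TRUE`), a character vector
#'   of report lines.
#' @export
explain_cell <- function(assessment, site_id, service_id, quiet = FALSE) {
  stopifnot(inherits(assessment, "cei_assessment"))
  cfg <- assessment$config
  row <- assessment$scores[assessment$scores$site_id == site_id &
                             assessment$scores$service_id == service_id, ,
                           drop = FALSE]
  if (nrow(row) == 0) {
    abort(sprintf("unknown cell: site '%s', service '%s'", site_id, service_id),
          class = "cei_data_error")
  }
  ref <- assessment$reference_points[
    assessment$reference_points$service_id == service_id, , drop = FALSE]
  scr <- assessment$screening[assessment$screening$service_id == service_id, ,
                              drop = FALSE]
  fs <- assessment$factor_scores[
    assessment$factor_scores$site_id == site_id &
      assessment$factor_scores$service_id == service_id, , drop = FALSE]
  flags <- if (is.na(row$flags) || row$flags == "") character() else {
    strsplit(row$flags, ";")[[1]]
  }

  num <- function(v, d = 4) ifelse(is.na(v), "NA", formatC(v, digits = d, format = "g"))
  lines <- c(
    sprintf("Cell: site %s, service %s (evaluation year %d)",
            site_id, service_id, cfg$evaluation_year),
    sprintf("Window: %d-%d; pooled observations: %d retained, %d excluded as outliers (k = %g)",
            ref$window_first, ref$window_last,
            sum(!scr$excluded), sum(scr$excluded), cfg$outlier_k)
  )
  site_scr <- scr[scr$site_id == site_id, , drop = FALSE]
  for (i in seq_len(nrow(site_scr))) {
    lines <- c(lines, sprintf("  %d: X = %s%s", site_scr$year[i],
                              num(site_scr$value[i]),
                              if (site_scr$excluded[i]) "  [excluded]" else ""))
  }
  lines <- c(lines,
    if (ref$fixed) {
      sprintf("Reference point X_R = %s (fixed by configuration)", num(ref$X_R))
    } else {
      sprintf("Reference point X_R = %s (site %s, year %d)",
              num(ref$X_R), ref$source_site, ref$source_year)
    },
    sprintf("Present status: X = %s, x = X / X_R = %s", num(row$X), num(row$x)),
    sprintf("Trend: slope t = %s per year, se = %s, n = %d",
            num(row$slope), num(row$se), row$n_points),
    sprintf("  T = 5t (clamped to [-1, 1]) = %s; 95%% CI [%s, %s] (half-width 15 se)",
            num(row$T), num(row$T_lower), num(row$T_upper))
  )
  if (nrow(fs) > 0) {
    lines <- c(lines, "Factor scores:")
    for (i in seq_len(nrow(fs))) {
      lines <- c(lines, sprintf("  %-28s %s (%s)", fs$factor_id[i],
                                num(fs$score[i]), fs$basis[i]))
    }
    lines <- c(lines, sprintf("PR (weighted mean of scored factors) = %s",
                              num(row$PR)))
  } else {
    lines <- c(lines, "Factor scores: none declared for this service")
  }
  if ("PR_DEFAULTED" %in% flags) {
    lines <- c(lines,
               "  PR was not evaluated; the projection uses PR = 0 and reflects the trend only")
  }
  lines <- c(lines,
    sprintf("Future status: raw (1 + %g T + %g PR) x = %s%s",
            cfg$beta, 1 - cfg$beta, num(row$x_F_raw),
            if ("CLAMPED_FUTURE" %in% flags) {
              sprintf("; clamped to x_F = %s", num(row$x_F))
            } else ""),
    sprintf("Service score I = (x + x_F) / 2 = %s (%s scale)",
            num(row$I), cfg$report_scale),
    sprintf("Sustainability S = (x_F - x) / x = %s%s", num(row$S),
            if (!is.na(row$S)) sprintf(" (%+d%%)", round(100 * row$S)) else ""),
    sprintf("Flags: %s", if (length(flags) == 0) "none" else
      paste(flags, collapse = ", "))
  )
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
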