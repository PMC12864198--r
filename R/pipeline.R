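#' Validate study input tables
#'
#' Schema and range checks for the three input tables: ratings must be
#' positive with exactly 5 washout + 32 test lifts (8 per test object) per
#' participant-condition block; presence items must be integers 1..7, six
#' per participant; stream time stamps must be strictly increasing per
#' trial with sample spacing within 10% of the trial's nominal rate.
#' Reporting only: returns the issue list rather than raising.
#'
#' @param ratings Ratings table (see [simulate_ratings()] for the schema).
#' @param presence Presence table (`participant_id`, `item1`..`item6`).
#' @param streams Optional long stream table.
#' @return Data frame of issues (`code`, `where`, `message`); zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(ratings, presence = NULL, streams = NULL) {
  issues <- list()
  add <- function(code, where, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      code = code, where = where, message = message,
      stringsAsFactors = FALSE)
  }

  need <- c("participant_id", "condition", "object", "trial_index",
            "phase", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss) > 0) {
    add("ratings_missing_columns", "ratings",
        paste("missing:", paste(miss, collapse = ", ")))
  } else {
    if (any(!is.finite(ratings$rating)) || any(ratings$rating <= 0)) {
      add("rating_not_positive", "ratings",
          "ratings must be finite and > 0")
    }
    blocks <- split(ratings, list(ratings$participant_id,
                                  ratings$condition), drop = TRUE)
    for (b in blocks) {
      lbl <- paste0("participant ", b$participant_id[1], ", ",
                    b$condition[1])
      n_wash <- sum(b$phase == "washout")
      n_test <- sum(b$phase == "test")
      if (n_wash != 5 || n_test != 32) {
        add("trial_count_mismatch", lbl,
            sprintf("expected 5 washout + 32 test, got %d + %d",
                    n_wash, n_test))
      }
      cnt <- table(b$object[b$phase == "test"])
      test_objs <- setdiff(unique(b$object[b$phase == "test"]),
                           "medium_washout")
      if (length(test_objs) != 4 || any(cnt[test_objs] != 8)) {
        add("object_count_mismatch", lbl,
            "each test object must appear exactly 8 times")
      }
    }
  }

  if (!is.null(presence)) {
    item_cols <- paste0("item", 1:6)
    if (!all(item_cols %in% names(presence))) {
      add("presence_missing_columns", "presence",
          "need item1..item6")
    } else {
      items <- as.matrix(presence[, item_cols])
      bad <- !is.finite(items) | items < 1 | items > 7 |
        items != round(items)
      if (any(bad)) {
        rows <- unique(which(bad, arr.ind = TRUE)[, 1])
        add("presence_item_out_of_range",
            paste("participant",
                  paste(presence$participant_id[rows], collapse = ", ")),
            "items must be integers in 1..7")
      }
    }
  }

  if (!is.null(streams)) {
    ok <- tryCatch({check_stream_columns(streams); TRUE},
                   error = function(e) FALSE)
    if (!ok) {
      add("streams_missing_columns", "streams", "schema mismatch")
    } else {
      for (tr in split(streams, streams$trial_id)) {
        dt <- diff(tr$time_s)
        if (any(dt <= 0)) {
          add("time_not_monotone", tr$trial_id[1],
              "time stamps must strictly increase")
        } else {
          nominal <- stats::median(dt)
          if (any(abs(dt - nominal) > 0.1 * nominal)) {
            add("irregular_sampling", tr$trial_id[1],
                "sample spacing deviates >10% from nominal")
          }
        }
        if (nrow(tr) < 30) {
          add("too_few_samples", tr$trial_id[1],
              "trials need at least 30 samples")
        }
      }
    }
  }

  if (length(issues) == 0) {
    return(data.frame(code = character(0), where = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Read a study dataset from a directory of CSV files
#'
#' Expects `ratings.csv` and `presence.csv` (schemas as written by
#' [write_study()]) and optionally `streams.csv`.
#'
#' @param dir Directory containing the files.
#' @return A list with `ratings`, `presence`, `streams` (or `NULL`).
#' @export
read_study <- function(dir) {
  rat_path <- file.path(dir, "ratings.csv")
  if (!file.exists(rat_path)) stop("no ratings.csv in ", dir)
  ratings <- utils::read.csv(rat_path, stringsAsFactors = FALSE)
  pre_path <- file.path(dir, "presence.csv")
  presence <- if (file.exists(pre_path)) {
    utils::read.csv(pre_path, stringsAsFactors = FALSE)
  }
  str_path <- file.path(dir, "streams.csv")
  streams <- if (file.exists(str_path)) {
    utils::read.csv(str_path, stringsAsFactors = FALSE)
  }
  list(ratings = ratings, presence = presence, streams = streams)
}

# Winsorise per condition, gate on normality of the paired differences,
# and run the routed paired contrast. BF10 always comes from the JZS
# paired t formulation, mirroring the convention of reporting a Bayesian
# t test alongside rank-based frequentist results.
contrast_real_virtual <- function(real, virtual, label, z_limit = 3.29) {
  real_w <- winsorize(real, z_limit)
  virt_w <- winsorize(virtual, z_limit)
  gate <- shapiro_wilk_gate(real_w - virt_w)
  tt <- paired_t(real_w, virt_w)
  res <- list(
    label = label, n = tt$n,
    n_winsorized = sum(real_w != real) + sum(virt_w != virtual),
    shapiro_W = gate$W, shapiro_p = gate$p,
    method = if (gate$nonnormal) "wilcoxon" else "paired_t",
    mean_diff = tt$mean_diff, ci95 = tt$ci95,
    t = tt$t, df = tt$df, d_z = tt$d_z, bf10 = tt$bf10, p = tt$p
  )
  if (gate$nonnormal) {
    wx <- wilcoxon_signed_rank(real_w, virt_w)
    res$V <- wx$V
    res$p <- wx$p
  }
  res
}

# participant x condition means of a per-trial kinematic metric, valid
# trials only; expects metrics annotated with participant/condition.
aggregate_metric <- function(metrics, var) {
  ok <- metrics[metrics$valid, , drop = FALSE]
  agg <- stats::aggregate(ok[[var]],
                          list(participant_id = ok$participant_id,
                               condition = ok$condition), mean)
  names(agg)[3] <- var
  agg
}

paired_by_condition <- function(df, var) {
  wide <- stats::reshape(df, idvar = "participant_id",
                         timevar = "condition", direction = "wide")
  keep <- stats::complete.cases(wide)
  list(participant_id = wide$participant_id[keep],
       real = wide[keep, paste0(var, ".real")],
       virtual = wide[keep, paste0(var, ".virtual")],
       n_dropped = sum(!keep))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end chain: (optionally) simulate or load a
#' study, validate it, extract kinematic metrics from tracker streams,
#' compute z-scored ratings, SWI and presence scores, and run the full set
#' of comparisons: the SWI real-vs-virtual paired contrast, the four
#' kinematic contrasts (MRV, time to MRV, MLV, time to MLV), the
#' size x weight x condition within-subjects ANOVA on z-scored ratings,
#' and the presence regressions (virtual-block SWI on presence, and the
#' real-minus-virtual SWI difference on presence). Each contrast is
#' winsorised per condition and routed through a Shapiro-Wilk gate to a
#' paired t or Wilcoxon signed-rank test.
#'
#' @param config A [swi_config()]; governs the simulation when
#'   `input_dir` is `NULL` and supplies the seed recorded in the report.
#' @param input_dir Directory of CSV inputs ([read_study()] schema). When
#'   `NULL` (default) a synthetic study is generated from `config`.
#' @param out_dir Optional directory; when given, intermediate CSVs and
#'   `report.json` are written there.
#' @param streams Stream simulation scope passed to [simulate_study()]
#'   (`"test"`, `"all"`, `"none"`); `"none"` skips all kinematic analyses.
#' @return A list of class `swi_report`; see the elements `swi_contrast`,
#'   `kinematic_contrasts`, `anova`, `presence_regression`,
#'   `presence_diff_regression`, `scores`, `counts`.
#' @export
run_pipeline <- function(config = swi_config(), input_dir = NULL,
                         out_dir = NULL, streams = "test") {
  if (is.null(input_dir)) {
    study <- simulate_study(config, streams = streams)
    ratings <- study$ratings
    presence <- study$presence
    stream_df <- study$streams
    provenance <- list(source = "synthetic", seed = config$seed,
                       n_participants = config$n_participants)
  } else {
    inputs <- read_study(input_dir)
    ratings <- inputs$ratings
    presence <- inputs$presence
    stream_df <- inputs$streams
    provenance <- list(source = normalizePath(input_dir), seed = config$seed)
  }

  issues <- validate_inputs(ratings, presence, stream_df)
  fatal <- issues$code %in% c("ratings_missing_columns",
                              "streams_missing_columns",
                              "rating_not_positive")
  if (any(fatal)) {
    stop("input validation failed: ",
         paste(issues$message[fatal], collapse = "; "))
  }

  # scoring
  ztrials <- zscore_ratings(ratings)
  scores <- swi_scores(ratings)
  pres <- if (!is.null(presence)) presence_scores(presence)

  swi_pairs <- paired_by_condition(
    scores[, c("participant_id", "condition", "swi_score")], "swi_score")
  swi_contrast <- contrast_real_virtual(swi_pairs$real, swi_pairs$virtual,
                                        "swi_score")
  anova_tab <- rm_anova_ratings(ztrials)

  # kinematics
  kin_contrasts <- NULL
  metrics <- NULL
  n_invalid <- 0L
  if (!is.null(stream_df)) {
    metrics <- trial_metrics(stream_df)
    id_parts <- regmatches(
      metrics$trial_id,
      regexec("^p(\\d+)_(real|virtual)_t(\\d+)$", metrics$trial_id))
    if (any(lengths(id_parts) != 4)) {
      stop("stream trial_id must follow 'p<participant>_<condition>_t<k>'")
    }
    metrics$participant_id <- as.integer(vapply(id_parts, `[`, "", 2))
    metrics$condition <- vapply(id_parts, `[`, "", 3)
    n_invalid <- sum(!metrics$valid)

    kin_contrasts <- list()
    for (var in c("mrv_mm_s", "t_mrv_pct", "mlv_mm_s", "t_mlv_pct")) {
      pairs <- paired_by_condition(aggregate_metric(metrics, var), var)
      kin_contrasts[[var]] <- contrast_real_virtual(pairs$real,
                                                    pairs$virtual, var)
    }
    # the reach/lift velocity differences are more naturally read in m/s
    kin_contrasts$mrv_mm_s$mean_diff_m_s <-
      kin_contrasts$mrv_mm_s$mean_diff / 1000
    kin_contrasts$mlv_mm_s$mean_diff_m_s <-
      kin_contrasts$mlv_mm_s$mean_diff / 1000
  }

  # presence regressions
  presence_reg <- NULL
  presence_diff_reg <- NULL
  if (!is.null(pres) && nrow(pres) >= 4) {
    virt <- scores[scores$condition == "virtual", ]
    m <- merge(virt, pres, by = "participant_id")
    presence_reg <- simple_regression(m$presence_score, m$swi_score)
    dd <- data.frame(participant_id = swi_pairs$participant_id,
                     swi_diff = swi_pairs$real - swi_pairs$virtual)
    m2 <- merge(dd, pres, by = "participant_id")
    presence_diff_reg <- simple_regression(m2$presence_score, m2$swi_diff)
  }

  report <- structure(
    list(
      provenance = provenance,
      package_version = as.character(utils::packageVersion("swilift")),
      counts = list(
        n_participants = length(unique(ratings$participant_id)),
        n_rating_trials = nrow(ratings),
        n_stream_trials = if (is.null(metrics)) 0L else nrow(metrics),
        n_invalid_trials = n_invalid,
        n_validation_issues = nrow(issues)
      ),
      validation = issues,
      scores = scores,
      presence_scores = pres,
      swi_contrast = swi_contrast,
      kinematic_contrasts = kin_contrasts,
      anova = anova_tab,
      presence_regression = presence_reg,
      presence_diff_regression = presence_diff_reg
    ),
    class = "swi_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "swi_scores.csv"),
                     row.names = FALSE)
    if (!is.null(pres)) {
      utils::write.csv(pres, file.path(out_dir, "presence_scores.csv"),
                       row.names = FALSE)
    }
    if (!is.null(metrics)) {
      utils::write.csv(metrics, file.path(out_dir, "trial_metrics.csv"),
                       row.names = FALSE)
    }
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write an analysis report as JSON
#'
#' @param report A `swi_report` from [run_pipeline()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' @export
print.swi_report <- function(x, ...) {
  cat("SWI analysis report (", x$provenance$source, ", seed ",
      x$provenance$seed, ")\n", sep = "")
  cat("participants:", x$counts$n_participants,
      "| rating trials:", x$counts$n_rating_trials,
      "| invalid kinematic trials:", x$counts$n_invalid_trials, "\n\n")
  sc <- x$swi_contrast
  cat(sprintf(
    "SWI real - virtual: mean diff %.4g g/cm3, t(%d) = %.2f, p = %.3g, d_z = %.2f, BF10 = %.3g\n",
    sc$mean_diff, sc$df, sc$t, sc$p, sc$d_z, sc$bf10))
  if (!is.null(x$kinematic_contrasts)) {
    for (nm in names(x$kinematic_contrasts)) {
      k <- x$kinematic_contrasts[[nm]]
      cat(sprintf("%s (%s): diff %.4g, p = %.3g, d_z = %.2f\n",
                  nm, k$method, k$mean_diff, k$p, k$d_z))
    }
  }
  if (!is.null(x$presence_regression)) {
    pr <- x$presence_regression
    cat(sprintf(
      "presence -> SWI (virtual): beta = %.4g, R^2 = %.3f, p = %.3g, BF10 = %.3g\n",
      pr$beta, pr$r_sq, pr$p, pr$bf10))
  }
  invisible(x)
}
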