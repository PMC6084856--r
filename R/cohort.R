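#' Load a patient cohort table
#'
#' Reads a cohort CSV in the planning-table schema (demographics, jaw-plan
#' magnitudes in cm, pre/post AHI, narrowest velo-/laryngopharyngeal
#' cross-section metrics). Duplicated patient rows (same `id`) are
#' collapsed to the first occurrence with a warning.
#'
#' @param path CSV path with at least an `id` column.
#' @return data.frame of class `patient_cohort`, one row per patient.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed cohort CSV: ",
                                          conditionMessage(e)))
  if (!nrow(df)) stop("empty cohort file: ", path)
  if (is.null(df$id)) stop("cohort CSV must have an 'id' column")
  bad <- which(!stats::complete.cases(df["id"]))
  if (length(bad)) {
    stop("malformed cohort rows (missing id) at lines: ",
         paste(bad + 1L, collapse = ", "))
  }
  dup <- duplicated(df$id)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated patient row(s): id %s",
                    sum(dup), paste(unique(df$id[dup]), collapse = ", ")))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("patient_cohort", "data.frame")
  df
}

#' Cohort summary statistics for one column
#'
#' Sample statistics as reported in clinical planning tables: mean, sample
#' standard deviation (n-1 denominator), min, max. Rounding happens only at
#' report time.
#'
#' @param records a `patient_cohort` (or data.frame).
#' @param column column name.
#' @return list with `mean`, `sd`, `min`, `max`, `n`.
#' @export
cohort_summary <- function(records, column) {
  v <- records[[column]]
  if (is.null(v)) stop("no such column: ", column)
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 non-missing values in ", column)
  list(mean = mean(v), sd = sd(v), min = min(v), max = max(v),
       n = length(v))
}

#' Sher criterion for surgical success
#'
#' Success is a greater than 50% reduction of the apnea-hypopnea index
#' and/or a post-surgical AHI below 20 events per hour.
#'
#' @param ahi_pre,ahi_post AHI before/after surgery (events/h, >= 0).
#' @return logical scalar.
#' @export
sher_success <- function(ahi_pre, ahi_post) {
  stopifnot(ahi_pre >= 0, ahi_post >= 0)
  below20 <- ahi_post < 20
  if (ahi_pre == 0) {
    if (below20) return(TRUE)
    stop("relative AHI reduction undefined for ahi_pre = 0")
  }
  ((ahi_pre - ahi_post) / ahi_pre > 0.5) || below20
}

#' Paired two-sided t-test from the closed-form statistic
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the paired differences, df = n-1,
#' two-sided p from the Student t distribution. Zero-variance differences
#' with non-zero mean give infinite t and p = 0 with `degenerate = TRUE`;
#' all-zero differences give t = 0, p = 1.
#'
#' @param a,b paired numeric vectors of equal length n >= 2.
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- sd(d)
  md <- mean(d)
  if (s == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md,
                degenerate = TRUE))
  }
  t <- md / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1), mean_diff = md,
       degenerate = FALSE)
}

significance_bin <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "n.s."
}

#' Compare pre-, post-surgery and simulated airway profiles
#'
#' For each region (VPX, LPX) and each measure (area, AP, Lat), runs paired
#' t-tests over the cross-section stations for the three pairs pre/post,
#' pre/sim and post/sim, and bins p-values into the conventional
#' significance classes (***, **, *, n.s.). Profiles are matched on their
#' common stations (mismatched grids are intersected, with a note).
#'
#' @param pre_profile,post_profile,sim_profile `airway_profile` objects
#'   with regions tagged.
#' @param regions region tags to compare.
#' @return data.frame with columns region, measure, pair, t, df, p, signif,
#'   n_stations (2 regions x 3 measures x 3 pairs = 18 rows by default).
#' @export
compare_airways <- function(pre_profile, post_profile, sim_profile,
                            regions = c("VPX", "LPX")) {
  profs <- list(pre = pre_profile, post = post_profile, sim = sim_profile)
  measures <- c(area = "area_cm2", AP = "ap_cm", Lat = "lat_cm")
  pairs <- list(c("pre", "post"), c("pre", "sim"), c("post", "sim"))
  out <- list()
  for (rg in regions) {
    secs <- lapply(profs, function(p) {
      s <- p$sections[p$sections$region == rg, , drop = FALSE]
      s[order(s$station), , drop = FALSE]
    })
    if (any(vapply(secs, nrow, integer(1)) == 0L)) {
      warning("region ", rg, " empty in at least one profile; skipped")
      next
    }
    key <- function(s) round(s$station, 6)
    common <- Reduce(intersect, lapply(secs, key))
    if (length(common) < 2) {
      warning("fewer than 2 common stations in region ", rg, "; skipped")
      next
    }
    for (ms in names(measures)) {
      for (pr in pairs) {
        va <- secs[[pr[1]]][match(common, key(secs[[pr[1]]])),
                            measures[[ms]]]
        vb <- secs[[pr[2]]][match(common, key(secs[[pr[2]]])),
                            measures[[ms]]]
        tt <- paired_ttest(va, vb)
        out[[length(out) + 1]] <- data.frame(
          region = rg, measure = ms, pair = paste(pr, collapse = "/"),
          t = tt$t, df = tt$df, p = tt$p, signif = significance_bin(tt$p),
          n_stations = length(common), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Cohort table with aggregate rows
#'
#' Appends mean / std / min / max rows (computed over patients, sample sd)
#' to the numeric columns of a cohort table, rounding each column to the
#' given number of decimals at report time only.
#'
#' @param records a `patient_cohort`.
#' @param digits named vector of decimals per column, or a single default.
#' @return data.frame with `id` column extended by "mean", "std", "min",
#'   "max".
#' @export
cohort_table <- function(records, digits = 1) {
  df <- as.data.frame(records)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "id")
  agg <- data.frame(id = c("mean", "std", "min", "max"),
                    stringsAsFactors = FALSE)
  for (cl in num_cols) {
    v <- df[[cl]][!is.na(df[[cl]])]
    s <- if (length(v) >= 2) cohort_summary(df, cl) else
      list(mean = mean(v), sd = NA_real_, min = min(v), max = max(v))
    d <- if (length(digits) > 1 && cl %in% names(digits)) digits[[cl]]
         else if (length(digits) == 1) digits else 1
    agg[[cl]] <- round(c(s$mean, s$sd, s$min, s$max), d)
  }
  for (cl in setdiff(names(df), c("id", num_cols))) agg[[cl]] <- "-"
  df$id <- as.character(df$id)
  out <- rbind(df[, names(df)], agg[, names(df)])
  if (nrow(df) == 1) attr(out, "n1_flag") <- TRUE
  out
}

#' Per-patient and cohort evaluation report
#'
#' Emits the planning-table-shaped CSVs (per-patient rows plus
#' mean/std/min/max aggregate rows), Sher-criterion flags, and the
#' cross-section significance table, into a directory.
#'
#' @param records a `patient_cohort` with `ahi_pre`/`ahi_post` columns.
#' @param out_dir output directory.
#' @param comparisons optional data.frame from [compare_airways()].
#' @param digits decimals for aggregate rounding (see [cohort_table()]).
#' @return list with `table` (the aggregate table), `sher` (per-patient
#'   logical flags plus counts), written file paths.
#' @export
build_report <- function(records, out_dir, comparisons = NULL, digits = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohort_table(records, digits = digits)
  tab_path <- file.path(out_dir, "cohort_table.csv")
  write.csv(tab, tab_path, row.names = FALSE, quote = FALSE)
  sher <- NULL
  if (!is.null(records$ahi_pre) && !is.null(records$ahi_post)) {
    flags <- mapply(sher_success, records$ahi_pre, records$ahi_post)
    halved <- (records$ahi_pre - records$ahi_post) / records$ahi_pre > 0.5
    sher <- list(success = flags, n_success = sum(flags),
                 n_halved = sum(halved), n = length(flags))
    jsonlite::write_json(sher, file.path(out_dir, "sher.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(comparisons)) {
    write.csv(comparisons, file.path(out_dir, "airway_significance.csv"),
              row.names = FALSE, quote = FALSE)
  }
  list(table = tab, sher = sher, paths = list(table = tab_path))
}
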