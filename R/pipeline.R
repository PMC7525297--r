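#' Elliptical initialization mask for a phantom set
#'
#' Emulates the manual step of placing an ellipse over the TM on the white
#' image: the ground-truth TM ellipse is scaled by a covering factor and its
#' center and axes jittered by a seeded relative perturbation, then
#' rasterized.  The same mask initializes all four channels of the set.
#'
#' @param set a `multispectral_set`.
#' @param jitter_seed integer seed for the jitter draw.
#' @param cover_factor multiplicative margin on both semi-axes (default
#'   1.05, so the initial contour starts just outside the TM).
#' @param jitter_frac relative jitter bound on center and axes (default
#'   0.03; use 0 for the exact scaled ellipse).
#' @return list with `ellipse` (list `cx, cy, a, b, rot` plus `provenance`)
#'   and `mask` (logical matrix).
#' @export
make_init_mask <- function(set, jitter_seed = 0, cover_factor = 1.05,
                           jitter_frac = 0.03) {
  e <- set$spec$tm_ellipse
  jf <- with_local_seed(jitter_seed, runif(4, -jitter_frac, jitter_frac))
  # center jitter is relative to the semi-axes (a placement error of a few
  # percent of the TM size), not to the absolute frame coordinates
  ell <- list(cx = e$cx + e$a * jf[1], cy = e$cy + e$b * jf[2],
              a = e$a * cover_factor * (1 + jf[3]),
              b = e$b * cover_factor * (1 + jf[4]),
              rot = e$rot,
              provenance = "from_ground_truth_jittered")
  mask <- rasterize_ellipse(set$spec$width, set$spec$height,
                            ell$cx, ell$cy, ell$a, ell$b, ell$rot)
  if (!any(mask)) stop("initialization ellipse lies outside the image", call. = FALSE)
  list(ellipse = ell, mask = mask)
}

#' Segment every channel of a multispectral set
#'
#' Runs [evolve_contour_pyramid()] independently on each requested channel
#' from the identical initialization mask with identical parameters,
#' mirroring the protocol of comparing illuminations under one common mask
#' and iteration budget.  A failure in one channel (e.g. a vanished
#' contour) is recorded and does not abort the others.
#'
#' @param set a `multispectral_set`.
#' @param init logical initialization mask.
#' @param params a [contour_params()].
#' @param channels channels to segment (default all four).
#' @param coarse_scale passed to [evolve_contour_pyramid()].
#' @return named list of `segmentation_result` (or a `condition` object for
#'   a failed channel).
#' @export
segment_all_channels <- function(set, init,
                                 params = default_contour_params(c(set$spec$height, set$spec$width)),
                                 channels = c("white", "red", "green", "blue"),
                                 coarse_scale = 0.25) {
  out <- list()
  for (ch in channels) {
    out[[ch]] <- tryCatch(
      evolve_contour_pyramid(set$channels[[ch]], init, params, coarse_scale),
      error = function(e) e)
  }
  out
}

#' Aggregate per-channel metric records
#'
#' Arithmetic means and standard deviations of Dice and maximum Hausdorff
#' distance per channel, and rankings by mean Dice (descending) and mean
#' max HD (ascending).  Ties are broken by alphabetical channel name.
#' Records flagged invalid contribute their Dice (0) but no HD.
#'
#' @param records data frame of rows from [evaluate()].
#' @return list with `per_channel` (data frame: `channel`, `n`, `mean_dice`,
#'   `sd_dice`, `mean_max_hd`, `sd_max_hd`), `ranking_dice`, `ranking_hd`
#'   (character vectors, best first).
#' @export
summarize_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no records", call. = FALSE)
  chans <- sort(unique(records$channel))
  per <- do.call(rbind, lapply(chans, function(ch) {
    r <- records[records$channel == ch, ]
    data.frame(channel = ch, n = nrow(r),
               mean_dice = mean(r$dice), sd_dice = stats::sd(r$dice),
               mean_max_hd = mean(r$max_hd, na.rm = TRUE),
               sd_max_hd = stats::sd(r$max_hd, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  # order() is stable, and `per` is already alphabetical by channel
  ranking_dice <- per$channel[order(-per$mean_dice)]
  ranking_hd <- per$channel[order(per$mean_max_hd)]
  list(per_channel = per, ranking_dice = ranking_dice, ranking_hd = ranking_hd)
}

#' Run the full multispectral segmentation experiment
#'
#' Generates a cohort of `n` phantoms, builds one jittered elliptical
#' initialization per set, segments the requested channels of every set
#' with common parameters, evaluates each result against the set's
#' ground-truth TM mask, and aggregates per-channel statistics and
#' rankings.  Fully reproducible from `(spec, n, master_seed, params)`.
#'
#' @param spec base [phantom_spec()].
#' @param n cohort size (>= 1).
#' @param master_seed integer master seed (drives cohort geometry, phantom
#'   noise, and initialization jitter).
#' @param params a [contour_params()]; default scaled to the spec size.
#' @param channels channels to segment.
#' @param cover_factor,jitter_frac passed to [make_init_mask()].
#' @return an `experiment_report`: list with `records` (data frame),
#'   `summary` (from [summarize_records()]), `config`, `master_seed`, and
#'   `failures` (character vector describing any failed channel runs).
#' @export
run_experiment <- function(spec, n, master_seed,
                           params = default_contour_params(c(spec$height, spec$width)),
                           channels = c("white", "red", "green", "blue"),
                           cover_factor = 1.05, jitter_frac = 0.03) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  sets <- generate_cohort(spec, n, master_seed)
  records <- list()
  failures <- character(0)
  for (i in seq_len(n)) {
    set <- sets[[i]]
    init <- make_init_mask(set, jitter_seed = master_seed + i,
                           cover_factor = cover_factor,
                           jitter_frac = jitter_frac)
    segs <- segment_all_channels(set, init$mask, params, channels)
    for (ch in channels) {
      res <- segs[[ch]]
      if (inherits(res, "condition")) {
        # vanished contour: score the initialization boundary instead
        failures <- c(failures,
                      sprintf("phantom %d channel %s: %s", i, ch, conditionMessage(res)))
        rec <- data.frame(phantom_id = i, channel = ch, dice = 0,
                          max_hd = max_hausdorff(mask_boundary(init$mask),
                                                 mask_boundary(set$gt_tm_mask)),
                          n_pred_pixels = NA_integer_,
                          n_truth_pixels = sum(set$gt_tm_mask),
                          valid = FALSE, stringsAsFactors = FALSE)
      } else {
        rec <- evaluate(res$mask, set$gt_tm_mask, ch, i)
      }
      records[[length(records) + 1]] <- rec
    }
  }
  records <- do.call(rbind, records)
  structure(list(records = records,
                 summary = summarize_records(records),
                 config = list(spec = unclass(spec), n = n,
                               params = unclass(params),
                               channels = channels,
                               cover_factor = cover_factor,
                               jitter_frac = jitter_frac),
                 master_seed = master_seed,
                 failures = failures),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d phantoms x %d channels, master seed %d\n",
              x$config$n, length(x$config$channels), x$master_seed))
  print(x$summary$per_channel, row.names = FALSE)
  cat("ranking by mean Dice   :", paste(x$summary$ranking_dice, collapse = " > "), "\n")
  cat("ranking by mean max HD :", paste(x$summary$ranking_hd, collapse = " < "), "\n")
  if (length(x$failures)) cat("failures:", length(x$failures), "\n")
  invisible(x)
}

#' Write an experiment report to disk
#'
#' `records.csv` holds the per-(phantom, channel) metric table;
#' `report.json` the per-channel summary, rankings, config and seed.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @export
write_experiment_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_channel = report$summary$per_channel,
         ranking_dice = report$summary$ranking_dice,
         ranking_hd = report$summary$ranking_hd,
         master_seed = report$master_seed,
         failures = report$failures,
         config = report$config),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(dir)
}
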