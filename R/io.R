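# --- PNG plumbing ----------------------------------------------------------
# png::writePNG only emits 8-bit files, so the 16-bit grayscale writer is
# assembled here: zlib stream from memCompress (which, despite its name,
# produces an RFC1950 zlib stream), CRC32 from digest. Reading goes through
# png::readPNG, which handles 16-bit natively.

u32be <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)

crc32raw <- function(r) {
  h <- digest::digest(r, algo = "crc32", serialize = FALSE)
  u32be(Reduce(function(a, b) a * 16 + b, strtoi(strsplit(h, "")[[1]], 16L)))
}

png_chunk <- function(type, data) {
  c(u32be(length(data)), charToRaw(type), data,
    crc32raw(c(charToRaw(type), data)))
}

# levels: integer matrix in 0..65535, rows = image rows
write_png16 <- function(levels, path) {
  n <- nrow(levels); m <- ncol(levels)
  hi <- matrix(as.raw(levels %/% 256L), n, m)
  lo <- matrix(as.raw(levels %% 256L), n, m)
  rowdata <- matrix(as.raw(0), 2 * m + 1, n) # one column per image row
  rowdata[seq(2, 2 * m, 2), ] <- t(hi)
  rowdata[seq(3, 2 * m + 1, 2), ] <- t(lo)
  ihdr <- c(u32be(m), u32be(n), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.vector(rowdata), "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a luminance image as 16-bit grayscale PNG plus JSON sidecar
#'
#' Luminance in cd/m^2 cannot live in a PNG directly, so values are stored
#' as 16-bit gray levels and the sidecar `<path>.json` records the scale
#' (`cdm2_per_level`), the mean luminance, and the ppd.
#'
#' @param img a [luminance_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_luminance_image <- function(img, path) {
  stopifnot(is_luminance_image(img))
  v <- unclass(img); attributes(v) <- list(dim = dim(img))
  if (min(v) < 0) stop("luminance must be non-negative for storage")
  mx <- max(v)
  scale <- if (mx > 0) mx / 65535 else 1
  write_png16(matrix(as.integer(round(v / scale)), nrow(v), ncol(v)), path)
  jsonlite::write_json(
    list(mean_luminance = mean(v), ppd = attr(img, "ppd"),
         cdm2_per_level = scale, bits = 16L),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a luminance image written by [write_luminance_image()]
#'
#' 8-bit files are accepted with a warning; color PNGs are rejected.
#'
#' @param path PNG path; the sidecar `<path>.json` must exist.
#' @return A [luminance_image()].
#' @export
read_luminance_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  y <- png::readPNG(path, info = TRUE)
  if (length(dim(y)) == 3)
    stop("color image not supported: ", path)
  info <- attr(y, "info")
  bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (bits < 16)
    warning(path, ": ", bits, "-bit image accepted; luminance is quantized")
  values <- y * (2^bits - 1) * meta$cdm2_per_level
  luminance_image(unclass(values), meta$ppd)
}

#' Write a trace map as an 8-bit PNG (0 = background, 255 = traced)
#'
#' @param map a [trace_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_png <- function(map, path) {
  stopifnot(is_trace_map(map))
  m <- unclass(map); attributes(m) <- list(dim = dim(map))
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Read a trace map from a grayscale PNG
#'
#' Any nonzero pixel is traced. Color files are rejected; inputs with
#' intermediate gray levels (e.g. anti-aliased lines) are thresholded at
#' > 0 with a warning.
#'
#' @param path PNG path.
#' @param observer_id,image_id,condition identifiers attached to the map.
#' @return A [trace_map()].
#' @export
read_trace_png <- function(path, observer_id = NA, image_id = NA,
                           condition = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- png::readPNG(path)
  if (length(dim(y)) == 3)
    stop("color trace map not supported: ", path)
  if (any(y > 0 & y < 1))
    warning(path, ": non-binary gray levels thresholded at > 0")
  trace_map(unclass(y) > 0, observer_id = observer_id,
            image_id = image_id, condition = condition)
}

# --- manifests and configuration ------------------------------------------

#' Read and validate a trial manifest
#'
#' A manifest is a CSV with one row per drawing: columns `observer_id`,
#' `image_id`, `session` ("ground_truth" or "noisy"), `noise_family`,
#' `image_contrast`, `trace_path`, and optionally `center_sf` and
#' `stimulus_path`. `(observer_id, image_id, session)` must be unique for
#' ground-truth rows, and every referenced trace file must exist.
#'
#' @param path CSV path.
#' @param check_files verify referenced files exist (default TRUE).
#' @return A data.frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "image_id", "session", "noise_family",
            "image_contrast", "trace_path")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  bad <- !df$session %in% c("ground_truth", "noisy")
  if (any(bad))
    stop("unknown session tag(s): ", paste(unique(df$session[bad]),
                                           collapse = ", "))
  gt <- df[df$session == "ground_truth", ]
  if (anyDuplicated(gt[, c("observer_id", "image_id")]))
    stop("duplicate ground-truth rows for an (observer, image) pair")
  if (check_files) {
    dirbase <- dirname(path)
    rel <- !file.exists(df$trace_path) &
      file.exists(file.path(dirbase, df$trace_path))
    df$trace_path[rel] <- file.path(dirbase, df$trace_path[rel])
    gone <- !file.exists(df$trace_path)
    if (any(gone))
      stop("missing trace file(s): ",
           paste(utils::head(df$trace_path[gone], 3), collapse = ", "))
  }
  df
}

#' Pipeline run configuration
#'
#' Serializable bundle of every decision parameter of the pipeline:
#' scoring margin and rate correction, psychometric criterion and effective
#' trial count, patch category thresholds, and the master seed. Round-trips
#' losslessly through JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param margin_px,margin_fraction see [scoring_config()].
#' @param rate_correction see [scoring_config()].
#' @param include_cr see [proportion_correct()].
#' @param criterion psychometric threshold criterion.
#' @param effective_n effective trial count per aggregated p value used as
#'   psychometric weight (pixel counts are not independent trials).
#' @param salient_frac,some_lo,some_hi patch category thresholds.
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(margin_px = NULL, margin_fraction = NULL,
                       rate_correction = "loglinear", include_cr = FALSE,
                       criterion = 0.5, effective_n = 50,
                       salient_frac = 0.95, some_lo = 0.25, some_hi = 0.75,
                       seed = 1L) {
  if (is.null(margin_px) && is.null(margin_fraction)) margin_fraction <- 0.025
  structure(list(margin_px = margin_px, margin_fraction = margin_fraction,
                 rate_correction = rate_correction,
                 include_cr = isTRUE(include_cr),
                 criterion = criterion, effective_n = effective_n,
                 salient_frac = salient_frac, some_lo = some_lo,
                 some_hi = some_hi, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' @rdname run_config
#' @export
config_hash <- function(cfg) {
  digest::digest(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                  digits = NA, null = "null"),
                 algo = "crc32", serialize = FALSE)
}

scoring_config_from <- function(cfg) {
  scoring_config(margin_px = cfg$margin_px,
                 margin_fraction = if (is.null(cfg$margin_px))
                   cfg$margin_fraction else NULL,
                 rate_correction = cfg$rate_correction,
                 include_cr_in_pc = cfg$include_cr)
}

# Deterministic CSV writer: fixed float format, no quoting surprises, so
# re-running an identical pipeline is byte-identical.
write_csv_fixed <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the scoring + psychometric pipeline over a trial manifest
#'
#' Every noisy trial is scored against the SAME observer's ground-truth map
#' of the same image (the core pairing rule of the paradigm); trials
#' without a ground truth are skipped and reported. Scores are aggregated
#' per (noise family, contrast) and a max-scaled cumulative Gaussian is
#' fitted per family with at least 3 contrast levels. Both output CSVs
#' embed the config hash and package version.
#'
#' @param manifest data.frame from [read_manifest()] (or a path to one).
#' @param config a [run_config()].
#' @param out_dir output directory; created if needed. `scores.csv` and
#'   `fits.csv` are written there.
#' @return Invisibly, a list with `scores`, `fits`, and `skipped`
#'   data.frames.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  version <- as.character(utils::packageVersion("tracescore"))
  scfg <- scoring_config_from(config)

  if (nrow(manifest) == 0) {
    warning("empty manifest: writing empty outputs")
    scores <- data.frame()
    fits <- data.frame()
    write_csv_fixed(scores, file.path(out_dir, "scores.csv"))
    write_csv_fixed(fits, file.path(out_dir, "fits.csv"))
    return(invisible(list(scores = scores, fits = fits,
                          skipped = data.frame())))
  }

  gt_rows <- manifest[manifest$session == "ground_truth", ]
  gt_key <- paste(gt_rows$observer_id, gt_rows$image_id)
  noisy <- manifest[manifest$session == "noisy", ]
  noisy <- noisy[order(noisy$observer_id, noisy$image_id), ]

  cache <- new.env(parent = emptyenv())
  load_map <- function(p) {
    m <- get0(p, envir = cache, inherits = FALSE)
    if (is.null(m)) {
      m <- read_trace_png(p)
      assign(p, m, envir = cache)
    }
    m
  }

  rows <- list(); skipped <- list()
  for (r in seq_len(nrow(noisy))) {
    d <- noisy[r, ]
    k <- match(paste(d$observer_id, d$image_id), gt_key)
    if (is.na(k)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(observer_id = d$observer_id, image_id = d$image_id,
                   reason = "no ground-truth map")
      next
    }
    cnt <- score_traces(load_map(gt_rows$trace_path[k]),
                        load_map(d$trace_path), scfg)
    meas <- sdt_measures(cnt, correction = config$rate_correction,
                         include_cr = config$include_cr)
    rows[[length(rows) + 1]] <- data.frame(
      observer_id = d$observer_id, image_id = d$image_id,
      noise_family = d$noise_family, image_contrast = d$image_contrast,
      hits = cnt$hits, misses = cnt$misses, fa = cnt$fa, cr = cnt$cr,
      margin_px = attr(cnt, "margin_px"),
      p = meas$p, dprime = meas$dprime, c = meas$c)
  }
  scores <- if (length(rows)) do.call(rbind, rows) else data.frame()
  skipped <- if (length(skipped)) do.call(rbind, skipped) else data.frame()
  if (nrow(skipped))
    message(nrow(skipped), " noisy trial(s) skipped (no ground truth)")

  fits <- data.frame()
  if (nrow(scores)) {
    for (fam in sort(unique(scores$noise_family))) {
      sub <- scores[scores$noise_family == fam, ]
      agg <- stats::aggregate(p ~ image_contrast, data = sub, FUN = mean)
      cnts <- stats::aggregate(p ~ image_contrast, data = sub, FUN = length)
      if (nrow(agg) < 3) next
      pd <- scale_by_max(psychometric_data(
        agg$image_contrast, agg$p, weights = cnts$p * config$effective_n))
      fit <- fit_cumulative_gaussian(pd, criterion = config$criterion)
      fits <- rbind(fits, data.frame(
        noise_family = fam, pmax = fit$pmax, mu = fit$mu,
        sigma = fit$sigma, lambda = fit$lambda,
        threshold = fit$threshold, deviance = fit$gof$deviance,
        degenerate = fit$gof$degenerate))
    }
  }
  if (nrow(scores)) { scores$config_hash <- hash; scores$version <- version }
  if (nrow(fits)) { fits$config_hash <- hash; fits$version <- version }
  write_csv_fixed(scores, file.path(out_dir, "scores.csv"))
  write_csv_fixed(fits, file.path(out_dir, "fits.csv"))
  invisible(list(scores = scores, fits = fits, skipped = skipped))
}
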