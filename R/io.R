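#' Read wing-score data from delimited text
#'
#' Two dialects are supported and auto-detected from the header:
#' * per-wing: columns `genotype,score`, one row per scored wing, score in
#'   0-5 or B;
#' * aggregated: columns `genotype,s0,s1,s2,s3,s4,s5,B`, one row per
#'   genotype with per-category counts.
#'
#' Lines starting with `#` are comments. Tab- or comma-separated files are
#' both accepted.
#'
#' @param path file path.
#' @return per-wing dialect: a records data frame (for
#'   [tabulate_scores()]); aggregated dialect: a named list of
#'   [score_table] objects. Use [as_score_tables()] to get tables either
#'   way.
#' @export
read_score_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 50)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  if (length(first) == 0) stop("empty score file", call. = FALSE)
  sep <- if (grepl("\t", first[1])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  per_wing <- identical(sort(intersect(names(df), c("genotype", "score"))),
                        c("genotype", "score"))
  agg_cols <- c("genotype", paste0("s", 0:5), "B")
  aggregated <- all(agg_cols %in% names(df))
  if (per_wing && !aggregated) {
    df$score <- normalize_scores(df$score)
    return(df)
  }
  if (aggregated) {
    out <- lapply(seq_len(nrow(df)), function(i) {
      cnt <- suppressWarnings(as.numeric(df[i, c(paste0("s", 0:5), "B")]))
      if (any(is.na(cnt))) {
        stop(sprintf("non-numeric count in row %d of %s", i, path),
             call. = FALSE)
      }
      score_table(df$genotype[i], cnt)
    })
    names(out) <- df$genotype
    return(out)
  }
  stop(sprintf(
    "unrecognized score file header in %s (need genotype,score or genotype,s0..s5,B)",
    path), call. = FALSE)
}

#' Coerce score input to a named list of score tables
#'
#' @param x per-wing records data frame or a named list of [score_table]s
#'   (both as returned by [read_score_csv()]).
#' @return named list of [score_table] objects.
#' @export
as_score_tables <- function(x) {
  if (is.data.frame(x)) return(tabulate_scores(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "score_table")))
  x
}

#' Write wing-score records (per-wing dialect)
#' @param records data frame with `genotype` and `score` columns.
#' @param path output path.
#' @export
write_score_records <- function(records, path) {
  utils::write.csv(records[, c("genotype", "score")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write score tables (aggregated dialect)
#' @param tables named list of [score_table] objects.
#' @param path output path.
#' @export
write_score_tables <- function(tables, path) {
  rows <- do.call(rbind, lapply(tables, function(t) {
    data.frame(genotype = t$genotype, t(as.integer(t$counts)),
               stringsAsFactors = FALSE)
  }))
  names(rows) <- c("genotype", paste0("s", 0:5), "B")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- images and masks ------------------------------------------------------

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  )
  if (length(dim(v)) == 3) v <- v[, , 1] # first plane of multi-channel file
  v
}

#' Read a single-channel image (TIFF or PNG) as an intensity matrix
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix with intensities in \[0, 1\].
#' @export
read_channel <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  read_raster(path)
}

#' Write a single-channel intensity matrix as 32-bit float TIFF or PNG
#' @param x numeric matrix with values in \[0, 1\].
#' @param path destination ending in .tif/.tiff (float) or .png (16-bit).
#' @export
write_channel <- function(x, path) {
  stopifnot(is.matrix(x))
  x <- pmin(pmax(x, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 32),
    png = png::writePNG(x, path),
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  )
  invisible(path)
}

#' Read a chromosome mask image (nonzero = chromosome)
#' @param path mask image path (PNG or TIFF).
#' @return a [chromosome_mask] with provenance `"file"`.
#' @export
read_mask <- function(path) {
  v <- read_channel(path)
  chromosome_mask(v > 0.5, "file")
}

#' Write a chromosome mask as an 8-bit 0/255 PNG
#' @param mask a [chromosome_mask].
#' @param path destination `.png` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "chromosome_mask"))
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

# --- batch manifest --------------------------------------------------------

#' Read a batch manifest and load its images and masks
#'
#' The manifest is a CSV with columns `image_id,group,dapi_path,
#' ch1_name,ch1_path[,ch2_name,ch2_path][,mask_path]`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return list with `images` (list of [chromosome_image]) and `masks`
#'   (named list of [chromosome_mask], possibly empty).
#' @export
read_batch_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("image_id", "group", "dapi_path", "ch1_name", "ch1_path")
  if (!all(need %in% names(df))) {
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ",")),
         call. = FALSE)
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  images <- list()
  masks <- list()
  for (i in seq_len(nrow(df))) {
    chans <- list(dapi = read_channel(resolve(df$dapi_path[i])))
    chans[[df$ch1_name[i]]] <- read_channel(resolve(df$ch1_path[i]))
    if ("ch2_name" %in% names(df) && !is.na(df$ch2_name[i]) &&
        nzchar(df$ch2_name[i])) {
      chans[[df$ch2_name[i]]] <- read_channel(resolve(df$ch2_path[i]))
    }
    slide <- if ("slide" %in% names(df) && !is.na(df$slide[i])) {
      as.character(df$slide[i])
    } else ""
    images[[i]] <- chromosome_image(chans, image_id = df$image_id[i],
                                    group = df$group[i], slide = slide)
    if ("mask_path" %in% names(df) && !is.na(df$mask_path[i]) &&
        nzchar(df$mask_path[i])) {
      masks[[df$image_id[i]]] <- read_mask(resolve(df$mask_path[i]))
    }
  }
  list(images = images, masks = masks)
}

#' Write a simulated spread batch to disk with a manifest
#'
#' Writes one float TIFF per channel, a ground-truth mask PNG per spread,
#' and a manifest CSV consumable by [read_batch_manifest()].
#'
#' @param batch list of `synthetic_spread` objects from
#'   [simulate_polytene_batch()].
#' @param dir output directory (created if missing).
#' @return path of the written manifest.
#' @export
write_spread_batch <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(batch, function(sp) {
    id <- sp$image$image_id
    chans <- sp$image$channels
    dapi_path <- sprintf("%s_dapi.tif", id)
    write_channel(chans[[1]], file.path(dir, dapi_path))
    others <- names(chans)[-1]
    ch1 <- others[1]
    ch1_path <- sprintf("%s_%s.tif", id, ch1)
    write_channel(chans[[ch1]], file.path(dir, ch1_path))
    ch2 <- if (length(others) > 1) others[2] else NA_character_
    ch2_path <- NA_character_
    if (!is.na(ch2)) {
      ch2_path <- sprintf("%s_%s.tif", id, ch2)
      write_channel(chans[[ch2]], file.path(dir, ch2_path))
    }
    mask_path <- sprintf("%s_mask.png", id)
    write_mask(sp$truth_mask, file.path(dir, mask_path))
    data.frame(image_id = id, group = sp$image$group,
               dapi_path = dapi_path, ch1_name = ch1, ch1_path = ch1_path,
               ch2_name = ch2, ch2_path = ch2_path, mask_path = mask_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}
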