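# Image, manifest, config and checkpoint I/O.
#
# Default image format is the portable graymap (PGM, binary P5 or plain-text
# P2): 8-bit grayscale, readable with base R alone. PNG is supported when the
# 'png' package is installed. Intensities are stored as 8-bit and mapped
# to/from [0, 1] by dividing by 255.

.manifestColumns <- c("patient_id", "label", "stage", "frame_index", "path",
                      "split")

#' Read and write grayscale images
#'
#' `writeGrayImage()` quantizes a `[0, 1]` intensity matrix to 8 bits and
#' writes it; `readGrayImage()` reads it back as a matrix in `[0, 1]`.
#' Format is chosen by extension: `.pgm` (default, base R) or `.png`
#' (requires the optional `png` package). `ascii = TRUE` writes plain-text
#' (P2) graymaps.
#'
#' @param image numeric matrix with values in `[0, 1]` (rows = image rows).
#' @param path file path ending in `.pgm` or `.png`.
#' @param ascii write a plain-text P2 graymap instead of binary P5.
#' @return `readGrayImage()` returns a numeric matrix in `[0, 1]`;
#'   `writeGrayImage()` returns `path` invisibly.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' p <- file.path(tempdir(), "frame.pgm")
#' writeGrayImage(img, p)
#' max(abs(readGrayImage(p) - img)) <= 1 / 255
#' @export
writeGrayImage <- function(image, path, ascii = FALSE) {
  .assertImage(image)
  q <- as.integer(pmin(255, pmax(0, floor(image * 255 + 0.5))))
  q <- matrix(q, nrow(image), ncol(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package; use a .pgm path instead",
           call. = FALSE)
    }
    png::writePNG(q / 255, path)
    return(invisible(path))
  }
  if (ext != "pgm") stop("unsupported image extension: .", ext, call. = FALSE)
  raster <- as.vector(t(q))  # PGM rasters are row-major
  con <- file(path, "wb")
  on.exit(close(con))
  if (ascii) {
    writeLines(c("P2", paste(ncol(image), nrow(image)), "255",
                 paste(raster, collapse = "\n")), con)
  } else {
    writeLines(c("P5", paste(ncol(image), nrow(image)), "255"), con)
    writeBin(as.raw(raster), con)
  }
  invisible(path)
}

#' @rdname writeGrayImage
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    }
    return(a)
  }
  if (ext != "pgm") stop("unsupported image extension: .", ext, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) {
    stop("not a P2/P5 graymap: ", path, call. = FALSE)
  }
  tokens <- character(0)
  # header tokens: width height maxval (comments allowed)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated graymap header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) next
    tok <- ch
    repeat {
      ch <- readChar(con, 1L)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      tok <- paste0(tok, ch)
    }
    tokens <- c(tokens, tok)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P5") {
    raster <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    raster <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  t(matrix(raster, nrow = w, ncol = h)) / maxval
}

#' Read and write dataset manifests
#'
#' A manifest is a `data.frame` with one row per image and columns
#' `patient_id`, `label` (`pCR`/`non-pCR`), `stage` (`pre`/`post1`),
#' `frame_index` (0-based), `path`, `split` (`train`/`test`/`unassigned`);
#' an optional `augment_seed` column marks upsampled duplicates.
#'
#' @param manifest a manifest `data.frame`.
#' @param path CSV file path.
#' @return `readManifest()` returns the validated manifest;
#'   `writeManifest()` returns `path` invisibly.
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest)
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  validateManifest(m)
  m
}

#' @rdname writeManifest
#' @export
validateManifest <- function(manifest) {
  if (!is.data.frame(manifest)) stop("manifest must be a data.frame",
                                     call. = FALSE)
  miss <- setdiff(.manifestColumns, names(manifest))
  if (length(miss)) {
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(manifest$label %in% c("pCR", "non-pCR"))) {
    stop("manifest labels must be 'pCR' or 'non-pCR'", call. = FALSE)
  }
  if (!all(manifest$stage %in% c("pre", "post1"))) {
    stop("manifest stages must be 'pre' or 'post1'", call. = FALSE)
  }
  if (!all(manifest$split %in% c("train", "test", "unassigned"))) {
    stop("manifest split must be train/test/unassigned", call. = FALSE)
  }
  lab <- unique(manifest[, c("patient_id", "label")])
  if (anyDuplicated(lab$patient_id)) {
    stop("a patient carries more than one label", call. = FALSE)
  }
  invisible(manifest)
}

#' Load paired two-stage samples from a manifest
#'
#' Pairs each patient's `pre` and `post1` frames by `frame_index` and reads
#' the images. Rows flagged with an `augment_seed` (created by
#' [upsampleMinority()]) are re-rendered through a seeded geometric transform
#' when an [AugmentConfig-class] is supplied.
#'
#' @param manifest a manifest `data.frame` (see [readManifest()]).
#' @param split which split to load (`"train"`, `"test"`, or `NULL` for all).
#' @param baseDir optional directory that relative `path`s are resolved
#'   against.
#' @param augment optional [AugmentConfig-class] used for `augment_seed`
#'   rows.
#' @return A list of paired samples; each element has fields `pre`, `post`
#'   (matrices), `label`, `patient_id`, `frame_index`.
#' @export
loadPairedSamples <- function(manifest, split = NULL, baseDir = NULL,
                              augment = NULL) {
  validateManifest(manifest)
  m <- manifest
  if (!is.null(split)) m <- m[m$split == split, , drop = FALSE]
  if (nrow(m) == 0L) stop("no manifest rows in the requested split",
                          call. = FALSE)
  key <- paste(m$patient_id, m$frame_index, sep = "\r")
  pre <- m[m$stage == "pre", , drop = FALSE]
  post <- m[m$stage == "post1", , drop = FALSE]
  kPre <- paste(pre$patient_id, pre$frame_index, sep = "\r")
  kPost <- paste(post$patient_id, post$frame_index, sep = "\r")
  if (!setequal(kPre, kPost) || anyDuplicated(kPre) || anyDuplicated(kPost)) {
    stop("manifest frames do not pair one-to-one across stages; ",
         "each patient needs matching pre/post1 frame_index values",
         call. = FALSE)
  }
  post <- post[match(kPre, kPost), , drop = FALSE]
  resolve <- function(p) if (is.null(baseDir)) p else file.path(baseDir, p)
  readOne <- function(p) {
    p <- resolve(p)
    if (!file.exists(p)) stop("image file missing: ", p, call. = FALSE)
    readGrayImage(p)
  }
  hasAug <- "augment_seed" %in% names(pre)
  lapply(seq_len(nrow(pre)), function(i) {
    s <- list(pre = readOne(pre$path[i]), post = readOne(post$path[i]),
              label = pre$label[i], patient_id = pre$patient_id[i],
              frame_index = pre$frame_index[i])
    if (hasAug && !is.na(pre$augment_seed[i]) && !is.null(augment)) {
      s <- .withSeed(pre$augment_seed[i], geometricAugment(s, augment))
    }
    s
  })
}

#' Read and write configuration files
#'
#' Configurations serialize to plain lists keyed by section (`synthetic`,
#' `model`, `train`, `augment`). JSON is the default on-disk format; YAML is
#' used for `.yaml`/`.yml` paths when the optional `yaml` package is
#' installed.
#'
#' @param config a named list of sections, each either a plain list or one of
#'   the package's S4 configuration objects.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `readConfigFile()` returns a named list; section lists can be
#'   revived with [modelConfigFromList()] and friends.
#' @export
writeConfigFile <- function(config, path) {
  config <- lapply(config, function(x) if (isS4(x)) configAsList(x) else x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the 'yaml' package; use .json", call. = FALSE)
    }
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeConfigFile
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Convert configuration objects to and from plain lists
#'
#' @param x a [SyntheticConfig-class], [ModelConfig-class],
#'   [Hyperparams-class] or [AugmentConfig-class].
#' @return `configAsList()` returns a named list of slot values.
#' @export
configAsList <- function(x) {
  stopifnot(isS4(x))
  out <- lapply(slotNames(class(x)), function(s) slot(x, s))
  names(out) <- slotNames(class(x))
  out
}

.fromList <- function(constructor, values, rename = NULL) {
  values <- values[!vapply(values, is.null, logical(1))]
  keep <- intersect(names(values), names(formals(constructor)))
  do.call(constructor, values[keep])
}

#' @rdname configAsList
#' @param values a named list as produced by `configAsList()` or parsed from
#'   a config file.
#' @export
modelConfigFromList <- function(values) .fromList(ModelConfig, values)

#' @rdname configAsList
#' @export
syntheticConfigFromList <- function(values) .fromList(SyntheticConfig, values)

#' @rdname configAsList
#' @export
hyperparamsFromList <- function(values) .fromList(Hyperparams, values)

#' @rdname configAsList
#' @export
augmentConfigFromList <- function(values) .fromList(AugmentConfig, values)

#' Save and load model checkpoints
#'
#' A checkpoint is a single serialized parameter archive plus a JSON sidecar
#' (`<path>.json`) recording the full model configuration.
#'
#' @param model a [DBNNModel-class].
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `loadCheckpoint()` returns the restored [DBNNModel-class];
#'   `saveCheckpoint()` returns `path` invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "DBNNModel"))
  saveRDS(list(params = model@params, state = model@state, mode = model@mode),
          path)
  jsonlite::write_json(configAsList(model@config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  blob <- readRDS(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing config sidecar: ", side, call. = FALSE)
  cfg <- modelConfigFromList(jsonlite::read_json(side, simplifyVector = TRUE))
  new("DBNNModel", config = cfg, params = blob$params, state = blob$state,
      mode = blob$mode)
}
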