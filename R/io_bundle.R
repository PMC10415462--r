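# On-disk formats: EDF for EEG (with a JSON events sidecar), TSV for BOLD /
# covariates / maps, JSON for ground truth and reports. The bundle layout is
# self-describing and byte-deterministic for a given design.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a sensor recording as EDF plus JSON events sidecar
#'
#' Standard EDF: 16-bit samples with per-channel physical scaling (the
#' stored resolution is (phys_max - phys_min) / 65535, so the round-trip
#' error is bounded by half of that). Events, condition and the exact
#' sample count are written to `<path>.json`.
#'
#' @param rec a `sensor_recording`.
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  rate <- rec$rate
  rc_assert(abs(rate - round(rate)) < 1e-9, "EDF writer needs an integer rate")
  rate <- as.integer(round(rate))
  S <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  n_rec <- ceiling(n_samp / rate)
  data <- rec$data
  if (n_rec * rate > n_samp)
    data <- cbind(data, matrix(0, S, n_rec * rate - n_samp))

  # quantize with exactly the physical range stored in the header
  pmaxs <- signif(pmax(apply(abs(data), 1, max), 1e-6), 6)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.pad(x, width), con, eos = NULL)
  wr("0", 8); wr("synthetic subject", 80); wr("synthetic recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * S, 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(S, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(S)) wr("AgAgCl electrode", 80)
  for (i in seq_len(S)) wr("uV", 8)
  for (i in seq_len(S)) wr(sprintf("%.6g", -pmaxs[i]), 8)
  for (i in seq_len(S)) wr(sprintf("%.6g", pmaxs[i]), 8)
  for (i in seq_len(S)) wr(-dig_max, 8)
  for (i in seq_len(S)) wr(dig_max, 8)
  for (i in seq_len(S)) wr("", 80)
  for (i in seq_len(S)) wr(rate, 8)   # samples per record
  for (i in seq_len(S)) wr("", 32)    # per-signal reserved
  dig <- round(sweep(data, 1, dig_max / pmaxs, `*`))
  dig <- pmin(pmax(dig, -dig_max), dig_max)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * rate + 1):(r * rate), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  sidecar <- list(tr_triggers_s = rec$events$tr_triggers_s,
                  cardiac_s = rec$events$cardiac_s,
                  gswd_s = rec$events$gswd_s,
                  condition = rec$condition, n_samples = n_samp,
                  rate = rate)
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path the `.edf` file; the `<path>.json` sidecar must exist.
#' @return A `sensor_recording`.
#' @export
read_edf <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    rc_abort(paste0("missing events sidecar: ", side_path), "validation")
  side <- tryCatch(jsonlite::read_json(side_path, simplifyVector = TRUE),
                   error = function(e)
                     rc_abort(paste0("unreadable events sidecar: ", side_path),
                              "validation"))
  for (k in c("condition", "n_samples", "rate"))
    if (is.null(side[[k]]))
      rc_abort(paste0("events sidecar ", side_path, " lacks field '", k, "'"),
               "validation")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rd(8)
  S <- as.integer(rd(4))
  labels <- vapply(seq_len(S), function(i) rd(16), "")
  for (i in seq_len(S)) rd(80)
  for (i in seq_len(S)) rd(8)
  pmin_ <- vapply(seq_len(S), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(S), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(S), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(S), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(S)) rd(80)
  spr <- vapply(seq_len(S), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(S)) rd(32)
  rate <- spr[1]
  data <- matrix(0, S, n_rec * rate)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = S * rate, size = 2, endian = "little")
    data[, ((r - 1) * rate + 1):(r * rate)] <-
      matrix(raw, nrow = S, byrow = TRUE)
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- data * scale
  data <- data[, seq_len(side$n_samples), drop = FALSE]
  sensor_recording(data, side$rate, labels,
                   events = list(
                     tr_triggers_s = as.numeric(side$tr_triggers_s %||% numeric(0)),
                     cardiac_s = as.numeric(side$cardiac_s %||% numeric(0)),
                     gswd_s = as.numeric(side$gswd_s %||% numeric(0))),
                   condition = side$condition)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort bundle to disk
#'
#' Layout: `covariates.tsv`, `space/` (vertices, triangles, adjacency as
#' TSV), `leadfield.tsv`, `design.json`, and one `sub-XX/` directory per
#' subject with `eeg_<condition>.edf` (+ JSON sidecar), `bold.tsv`,
#' `confounds.tsv` and `ground_truth.json`.
#'
#' @param bundle a `cohort_bundle` from [simulate_cohort()].
#' @param path output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, overwrite = FALSE) {
  if (dir.exists(path) && length(list.files(path)) > 0 && !overwrite)
    rc_abort(paste0("output directory not empty: ", path,
                    " (use overwrite = TRUE)"), "validation")
  dir.create(file.path(path, "space"), recursive = TRUE, showWarnings = FALSE)
  sp <- bundle$space
  .write_tsv(data.frame(x = sp$coords[, 1], y = sp$coords[, 2],
                        z = sp$coords[, 3], region = sp$region_label,
                        subcortical = as.integer(sp$is_subcortical),
                        hemisphere = sp$hemisphere),
             file.path(path, "space", "vertices.tsv"))
  .write_tsv(as.data.frame(sp$triangles),
             file.path(path, "space", "triangles.tsv"))
  .write_tsv(as.data.frame(sp$adjacency),
             file.path(path, "space", "adjacency.tsv"))
  .write_tsv(bundle$covariates, file.path(path, "covariates.tsv"))
  .write_tsv(as.data.frame(bundle$leadfield$gain),
             file.path(path, "leadfield.tsv"))
  des <- bundle$design
  des$covariates <- NULL
  jsonlite::write_json(
    c(unclass(des), list(conditions = bundle$conditions)),
    file.path(path, "design.json"), digits = NA, auto_unbox = TRUE)
  for (i in seq_along(bundle$subjects)) {
    sd_ <- file.path(path, sprintf("sub-%02d", i))
    dir.create(sd_, showWarnings = FALSE)
    subj <- bundle$subjects[[i]]
    gt_out <- list()
    for (cond in bundle$conditions) {
      write_edf(subj[[paste0("eeg_", cond)]],
                file.path(sd_, paste0("eeg_", cond, ".edf")))
      gt <- subj[[paste0("gt_", cond)]]
      gt$sources <- NULL
      gt$artifacts <- NULL
      gt_out[[cond]] <- gt
    }
    if (!is.null(subj$bold)) {
      .write_tsv(as.data.frame(subj$bold$series), file.path(sd_, "bold.tsv"))
      .write_tsv(cbind(subj$bold$confounds,
                       location_note = ""), file.path(sd_, "confounds.tsv"))
      .write_tsv(data.frame(kind = subj$bold$location_kind),
                 file.path(sd_, "bold_locations.tsv"))
      gt_out$bold <- subj$bold$meta$ground_truth
    }
    jsonlite::write_json(gt_out, file.path(sd_, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a cohort bundle from disk
#'
#' @param path directory written by [write_bundle()].
#' @return A `cohort_bundle` (ground truth as stored; simulation sources are
#'   regenerable from the stored seeds).
#' @export
read_bundle <- function(path) {
  need <- c("design.json", "covariates.tsv", "leadfield.tsv",
            file.path("space", "vertices.tsv"))
  for (f in need)
    if (!file.exists(file.path(path, f)))
      rc_abort(paste0("bundle is missing /", f), "validation")
  des <- jsonlite::read_json(file.path(path, "design.json"),
                             simplifyVector = TRUE)
  conditions <- des$conditions
  vert <- read.delim(file.path(path, "space", "vertices.tsv"))
  tri <- as.matrix(read.delim(file.path(path, "space", "triangles.tsv")))
  adj <- as.matrix(read.delim(file.path(path, "space", "adjacency.tsv")))
  storage.mode(tri) <- "integer"; storage.mode(adj) <- "integer"
  dimnames(tri) <- NULL; dimnames(adj) <- NULL
  space <- structure(list(
    coords = unname(as.matrix(vert[, c("x", "y", "z")])),
    triangles = tri, adjacency = adj, region_label = vert$region,
    is_subcortical = vert$subcortical == 1, hemisphere = vert$hemisphere,
    n_cortical = sum(vert$subcortical == 0),
    n_subcortical = sum(vert$subcortical == 1),
    space_id = sprintf("space_c%d_s%d_loaded", sum(vert$subcortical == 0),
                       sum(vert$subcortical == 1)),
    seed = NA_integer_), class = "source_space")
  gain <- unname(as.matrix(read.delim(file.path(path, "leadfield.tsv"))))
  covariates <- read.delim(file.path(path, "covariates.tsv"))
  lf <- structure(list(gain = gain,
                       sensor_labels = sprintf("E%03d", seq_len(nrow(gain))),
                       sensor_coords = NULL,
                       model_meta = list(model = "loaded")),
                  class = "leadfield")
  rownames(lf$gain) <- lf$sensor_labels
  subjects <- list()
  i <- 1
  while (dir.exists(file.path(path, sprintf("sub-%02d", i)))) {
    sd_ <- file.path(path, sprintf("sub-%02d", i))
    subj <- list()
    for (cond in conditions) {
      f <- file.path(sd_, paste0("eeg_", cond, ".edf"))
      if (file.exists(f)) subj[[paste0("eeg_", cond)]] <- read_edf(f)
    }
    gt <- file.path(sd_, "ground_truth.json")
    if (file.exists(gt))
      subj$ground_truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
    bf <- file.path(sd_, "bold.tsv")
    if (file.exists(bf)) {
      series <- unname(as.matrix(read.delim(bf)))
      conf <- read.delim(file.path(sd_, "confounds.tsv"))
      kind <- read.delim(file.path(sd_, "bold_locations.tsv"))$kind
      subj$bold <- bold_recording(
        series, des$tr,
        confounds = conf[, c("trans_x", "trans_y", "trans_z",
                             "rot_x", "rot_y", "rot_z")],
        location_kind = kind, space_tag = "vertex",
        meta = list(subject_index = i,
                    ground_truth = subj$ground_truth$bold))
    }
    subjects[[i]] <- subj
    i <- i + 1
  }
  design <- des
  design$covariates <- covariates
  class(design) <- "cohort_design"
  structure(list(design = design, space = space, leadfield = lf,
                 covariates = covariates, subjects = subjects,
                 conditions = conditions),
            class = "cohort_bundle")
}

#' Checksums of every file in a bundle
#' @param path bundle directory.
#' @return Named md5 vector (relative paths, sorted).
#' @export
bundle_checksums <- function(path) {
  files <- sort(list.files(path, recursive = TRUE, full.names = FALSE))
  md5 <- tools::md5sum(file.path(path, files))
  names(md5) <- files
  md5
}
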