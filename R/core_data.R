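#' Survival label
#'
#' Time-to-event outcome for one patient: a positive follow-up time in months,
#' a binary event indicator (1 = event observed, 0 = right-censored), and the
#' endpoint the pair refers to (overall survival, disease-specific survival,
#' or disease-free interval).
#'
#' @param time Positive follow-up time in months.
#' @param event Event indicator, 0 or 1.
#' @param endpoint One of `"OS"`, `"DSS"`, `"DFI"`.
#' @return A `pcm_survival_label` list with fields `time`, `event`, `endpoint`.
#' @export
survival_label <- function(time, event, endpoint = c("OS", "DSS", "DFI")) {
  endpoint <- match.arg(endpoint)
  if (!is_scalar_number(time) || time <= 0) {
    stop_pcm("`time` must be a positive finite number (months)", "validation_error")
  }
  if (!(length(event) == 1L && event %in% c(0, 1))) {
    stop_pcm("`event` must be 0 (censored) or 1 (event)", "validation_error")
  }
  structure(
    list(time = as.numeric(time), event = as.integer(event), endpoint = endpoint),
    class = "pcm_survival_label"
  )
}

clinical_feature_names <- c(
  "age_scaled", "sex_female", "sex_male",
  "stage_I", "stage_II", "stage_III", "stage_IV", "stage_missing"
)

#' Encode routine clinical variables into a fixed-length vector
#'
#' Deterministic encoding of the clinical covariates used by the model: age,
#' sex and tumor stage. The layout has M = 8 slots:
#' `[age/100, sex_female, sex_male, stage_I, stage_II, stage_III, stage_IV,
#' stage_missing]`. Any input may be missing; a missing age contributes 0 with
#' its mask flag set, a missing stage activates the explicit `stage_missing`
#' slot (some cancers, e.g. lower-grade glioma, have no conventional staging
#' system, so stage-missingness must be representable rather than imputed).
#'
#' @param age Age in years, or `NA`.
#' @param sex `"male"` or `"female"` (case-insensitive), or `NA`.
#' @param stage Tumor stage `"I"`--`"IV"` (Roman or Arabic, optional
#'   `"Stage "` prefix), or `NA`.
#' @return A `pcm_clinical` list with `values`, `feature_names`,
#'   `missing_mask`, all of length 8.
#' @examples
#' encode_clinical(60, "female", "II")$values
#' @export
encode_clinical <- function(age = NA, sex = NA, stage = NA) {
  values <- numeric(8L)
  missing_mask <- integer(8L)

  if (length(age) != 1L || length(sex) != 1L || length(stage) != 1L) {
    stop_pcm("clinical inputs must be scalars", "validation_error")
  }

  if (is.na(age) || (is.character(age) && !nzchar(trimws(age)))) {
    missing_mask[1L] <- 1L
  } else {
    age <- suppressWarnings(as.numeric(age))
    if (!is.finite(age) || age < 0) {
      stop_pcm("`age` must be a nonnegative number of years or NA", "validation_error")
    }
    values[1L] <- age / 100
  }

  if (is.na(sex) || (is.character(sex) && !nzchar(trimws(sex)))) {
    missing_mask[2L:3L] <- 1L
  } else {
    sx <- tolower(trimws(as.character(sex)))
    if (sx %in% c("female", "f")) {
      values[2L] <- 1
    } else if (sx %in% c("male", "m")) {
      values[3L] <- 1
    } else {
      stop_pcm(sprintf("unrecognized sex value '%s'", sex), "validation_error")
    }
  }

  if (is.na(stage) || (is.character(stage) && !nzchar(trimws(stage)))) {
    values[8L] <- 1
  } else {
    st <- toupper(trimws(as.character(stage)))
    st <- sub("^STAGE\\s+", "", st)
    idx <- match(st, c("I", "II", "III", "IV", "1", "2", "3", "4"))
    if (is.na(idx)) {
      stop_pcm(sprintf("unrecognized tumor stage '%s' (expected I-IV)", stage),
               "validation_error")
    }
    if (idx > 4L) idx <- idx - 4L
    values[3L + idx] <- 1
  }

  structure(
    list(values = values, feature_names = clinical_feature_names,
         missing_mask = missing_mask),
    class = "pcm_clinical"
  )
}

#' Cancer-type code
#'
#' One-hot encoding of a cancer-type label against a fixed, sorted label set.
#' The label-to-index map is established once per cohort (sorted label order)
#' and persisted with trained models so the one-hot basis is stable between
#' training and inference. Indices are 1-based, following R convention.
#'
#' @param label Cancer-type label, e.g. `"BLCA"`.
#' @param levels Character vector of all labels in the cohort (will be sorted).
#' @return A `pcm_cancer_code` list with `index`, `label`, `onehot`, `levels`.
#' @export
cancer_type_code <- function(label, levels) {
  levels <- sort(unique(as.character(levels)))
  index <- match(as.character(label), levels)
  if (is.na(index)) {
    stop_pcm(sprintf("cancer label '%s' not among cohort levels", label),
             "validation_error")
  }
  onehot <- numeric(length(levels))
  onehot[index] <- 1
  structure(
    list(index = index, label = as.character(label), onehot = onehot,
         levels = levels),
    class = "pcm_cancer_code"
  )
}

#' Feature bag for one slide
#'
#' Container for one whole-slide image represented as an N x D matrix of patch
#' embeddings with tile coordinates. Coordinates are 0-based level-0 pixel
#' origins of each tile, `x` = column, with tiles covering the half-open
#' square `[x, x + patch_size_px) x [y, y + patch_size_px)`. Features are
#' snapped to float32 precision so that container round trips are
#' bit-identical.
#'
#' @param features Numeric N x D matrix of patch embeddings.
#' @param coords Integer N x 2 matrix of tile origins (columns `x`, `y`).
#' @param slide_id Slide identifier.
#' @param patch_size_px Patch edge length in pixels at the working
#'   magnification (default 224).
#' @param magnification Free-text magnification tag (default `"10x"`).
#' @param encoder_name Name of the patch encoder that produced the features.
#' @return A `pcm_bag` object.
#' @export
feature_bag <- function(features, coords, slide_id,
                        patch_size_px = 224L, magnification = "10x",
                        encoder_name = "unknown") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L) {
    stop_pcm("a feature bag must contain at least one patch", "validation_error")
  }
  check_finite(features, "features")
  coords <- as.matrix(coords)
  if (!identical(dim(coords), c(nrow(features), 2L))) {
    stop_pcm("`coords` must be an N x 2 matrix aligned with `features`",
             "dimension_error")
  }
  storage.mode(coords) <- "integer"
  if (anyDuplicated(coords) > 0L) {
    stop_pcm("tile coordinates must be unique within a bag", "validation_error")
  }
  structure(
    list(
      slide_id = as.character(slide_id),
      features = snap_float32(features),
      coords = coords,
      patch_size_px = as.integer(patch_size_px),
      magnification = as.character(magnification),
      encoder_name = as.character(encoder_name)
    ),
    class = "pcm_bag"
  )
}

#' @export
print.pcm_bag <- function(x, ...) {
  cat(sprintf("<pcm_bag> slide %s: %d patches x %d features (%s, %s)\n",
              x$slide_id, nrow(x$features), ncol(x$features),
              x$encoder_name, x$magnification))
  invisible(x)
}

#' Patient record
#'
#' Bundles everything the model consumes for one patient: one or more feature
#' bags (a patient can own several slides), the encoded clinical vector, the
#' cancer-type code and the survival label.
#'
#' @param patient_id Patient identifier.
#' @param bags List of [feature_bag()] objects (possibly stubs before loading).
#' @param clinical A [encode_clinical()] result.
#' @param cancer A [cancer_type_code()] result.
#' @param survival A [survival_label()] result.
#' @return A `pcm_patient` object.
#' @export
patient_record <- function(patient_id, bags, clinical, cancer, survival) {
  if (length(bags) < 1L) {
    stop_pcm("a patient record needs at least one feature bag", "validation_error")
  }
  dims <- unique(vapply(bags, function(b) {
    if (inherits(b, "pcm_bag")) ncol(b$features) else NA_integer_
  }, integer(1)))
  dims <- dims[!is.na(dims)]
  if (length(dims) > 1L) {
    stop_pcm(sprintf("all bags of a patient must share one feature dimension (saw %s)",
                     paste(dims, collapse = ", ")), "dimension_error")
  }
  structure(
    list(patient_id = as.character(patient_id), bags = bags,
         clinical = clinical, cancer = cancer, survival = survival),
    class = "pcm_patient"
  )
}

#' Cohort of patients
#'
#' @param patients List of [patient_record()] objects.
#' @param cancer_levels Sorted character vector of cancer-type labels.
#' @param D Feature dimension shared by all bags (may be `NA` for skeletons).
#' @return A `pcm_cohort` object with fields `patients`, `cancer_levels`,
#'   `K`, `D`.
#' @export
new_cohort <- function(patients, cancer_levels, D = NA_integer_) {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids) > 0L) {
    stop_pcm("patient ids must be unique within a cohort", "integrity_error")
  }
  cancer_levels <- sort(unique(as.character(cancer_levels)))
  for (p in patients) {
    if (p$cancer$index > length(cancer_levels)) {
      stop_pcm("cancer index exceeds number of cohort cancer levels",
               "validation_error")
    }
  }
  structure(
    list(patients = patients, cancer_levels = cancer_levels,
         K = length(cancer_levels), D = as.integer(D)),
    class = "pcm_cohort"
  )
}

#' @export
print.pcm_cohort <- function(x, ...) {
  cat(sprintf("<pcm_cohort> %d patients, %d cancer types (%s), D = %s\n",
              length(x$patients), x$K,
              paste(x$cancer_levels, collapse = ", "),
              ifelse(is.na(x$D), "?", x$D)))
  invisible(x)
}

manifest_required_cols <- c("patient_id", "slide_id", "cancer_type", "time", "event")

read_delim_sniff <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a cohort manifest
#'
#' Reads a delimited manifest (TSV or CSV, sniffed from the header line) with
#' one row per slide and builds a cohort skeleton: slides are grouped under
#' their patient, clinical variables are encoded, and the cancer label set is
#' mapped to indices in sorted-label order. Feature bags are *not* loaded;
#' each bag slot holds a stub carrying the slide id (see [load_cohort_bags()]).
#'
#' @param path Path to the manifest file.
#' @param schema Optional named character vector mapping canonical column
#'   names (`patient_id`, `slide_id`, `cancer_type`, `age`, `sex`, `stage`,
#'   `time`, `event`, `endpoint`) to the column names used in the file.
#' @return A `pcm_cohort` skeleton; the original rows are attached as a tibble
#'   in `attr(, "manifest")`.
#' @export
read_manifest <- function(path, schema = NULL) {
  df <- read_delim_sniff(path)
  cohort_from_manifest(df, schema = schema)
}

#' Build a cohort skeleton from a manifest data frame
#'
#' @param df Data frame with one row per slide.
#' @inheritParams read_manifest
#' @return A `pcm_cohort` skeleton.
#' @export
cohort_from_manifest <- function(df, schema = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(df)) {
        names(df)[names(df) == schema[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(manifest_required_cols, names(df))
  if (length(missing) > 0L) {
    stop_pcm(sprintf("manifest is missing required column(s): %s",
                     paste(missing, collapse = ", ")), "schema_error")
  }
  key <- paste(df$patient_id, df$slide_id, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    dupes <- unique(key[duplicated(key)])
    stop_pcm(sprintf("duplicate (patient_id, slide_id) pairs in manifest: %s",
                     paste(gsub("\r", "/", dupes), collapse = ", ")),
             "integrity_error")
  }
  bad_time <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_time) > 0L) {
    stop_pcm(sprintf("nonpositive or non-finite survival time in manifest row(s): %s",
                     paste(bad_time, collapse = ", ")), "validation_error")
  }

  levels <- sort(unique(as.character(df$cancer_type)))
  has <- function(col) col %in% names(df)
  patients <- list()
  for (pid in unique(df$patient_id)) {
    rows <- df[df$patient_id == pid, , drop = FALSE]
    if (length(unique(rows$cancer_type)) > 1L || length(unique(rows$time)) > 1L ||
        length(unique(rows$event)) > 1L) {
      stop_pcm(sprintf(
        "patient '%s' has inconsistent cancer_type/time/event across slides", pid),
        "integrity_error")
    }
    r1 <- rows[1L, ]
    bags <- lapply(rows$slide_id, function(sid) {
      structure(list(slide_id = as.character(sid)), class = "pcm_bag_stub")
    })
    endpoint <- if (has("endpoint") && !is.na(r1$endpoint)) r1$endpoint else "OS"
    rec <- patient_record(
      patient_id = pid,
      bags = bags,
      clinical = encode_clinical(
        age = if (has("age")) r1$age else NA,
        sex = if (has("sex")) r1$sex else NA,
        stage = if (has("stage")) r1$stage else NA
      ),
      cancer = cancer_type_code(r1$cancer_type, levels),
      survival = survival_label(r1$time, r1$event, endpoint)
    )
    patients[[length(patients) + 1L]] <- rec
  }
  out <- new_cohort(patients, levels)
  attr(out, "manifest") <- tibble::as_tibble(df)
  out
}

#' Express a cohort as a manifest tibble
#'
#' Inverse of [cohort_from_manifest()] up to column order: one row per slide
#' carrying the patient's survival label, cancer type and raw-ish clinical
#' values (age reconstructed from its scaled slot; sex/stage from their
#' one-hot slots).
#'
#' @param cohort A `pcm_cohort`.
#' @return A tibble with one row per slide.
#' @export
as_manifest <- function(cohort) {
  rows <- purrr::map_dfr(cohort$patients, function(p) {
    v <- p$clinical$values
    m <- p$clinical$missing_mask
    sex <- if (m[2L] == 1L) NA_character_ else if (v[2L] == 1) "female" else "male"
    stage <- if (v[8L] == 1) NA_character_ else c("I", "II", "III", "IV")[which(v[4:7] == 1)]
    age <- if (m[1L] == 1L) NA_real_ else v[1L] * 100
    tibble::tibble(
      patient_id = p$patient_id,
      slide_id = vapply(p$bags, function(b) b$slide_id, character(1)),
      cancer_type = p$cancer$label,
      age = age, sex = sex, stage = stage,
      time = p$survival$time, event = p$survival$event,
      endpoint = p$survival$endpoint
    )
  })
  rows
}

# ---- feature-bag container I/O -------------------------------------------

BAG_MAGIC <- charToRaw("PCMBAG1\n")
BAG_SCHEMA_VERSION <- 1L

#' Write a feature bag to a container file
#'
#' Single-file binary container: a magic tag, a JSON header describing the
#' datasets and attributes (slide id, dimensions, patch size, magnification,
#' encoder name, schema version), then the `features` dataset as little-endian
#' float32 (column-major) and the `coords` dataset as int32. Because
#' [feature_bag()] snaps features to float32 precision, a write/read round
#' trip is bit-identical.
#'
#' @param bag A `pcm_bag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bag <- function(bag, path) {
  stopifnot(inherits(bag, "pcm_bag"))
  header <- jsonlite::toJSON(list(
    schema_version = BAG_SCHEMA_VERSION,
    slide_id = bag$slide_id,
    n = nrow(bag$features), d = ncol(bag$features),
    patch_size_px = bag$patch_size_px,
    magnification = bag$magnification,
    encoder_name = bag$encoder_name,
    datasets = c("features", "coords")
  ), auto_unbox = TRUE)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BAG_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.numeric(bag$features), con, size = 4L, endian = "little")
  writeBin(as.integer(bag$coords), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a feature bag from a container file
#'
#' @param path Container file written by [write_bag()].
#' @param expected_dim Optional cohort-level feature dimension `D`; a mismatch
#'   raises a dimension error.
#' @return A `pcm_bag`.
#' @export
read_bag <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) {
    stop_pcm(sprintf("bag container '%s' does not exist", path), "format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(BAG_MAGIC))
  if (!identical(magic, BAG_MAGIC)) {
    stop_pcm(sprintf("'%s' is not a feature-bag container (bad magic)", path),
             "format_error")
  }
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L) {
    stop_pcm(sprintf("corrupted header in '%s'", path), "format_error")
  }
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen))),
    error = function(e) stop_pcm(sprintf("corrupted header in '%s'", path),
                                 "format_error")
  )
  for (field in c("n", "d", "slide_id", "datasets")) {
    if (is.null(header[[field]])) {
      stop_pcm(sprintf("container '%s' is missing header field '%s'", path, field),
               "format_error")
    }
  }
  if (!all(c("features", "coords") %in% header$datasets)) {
    stop_pcm(sprintf("container '%s' lacks required dataset(s): %s", path,
                     paste(setdiff(c("features", "coords"), header$datasets),
                           collapse = ", ")), "format_error")
  }
  n <- as.integer(header$n); d <- as.integer(header$d)
  if (!is.null(expected_dim) && d != expected_dim) {
    stop_pcm(sprintf("bag '%s' has D = %d but cohort expects D = %d",
                     header$slide_id, d, expected_dim), "dimension_error")
  }
  feats <- readBin(con, "numeric", n = n * d, size = 4L, endian = "little")
  coords <- readBin(con, "integer", n = n * 2L, size = 4L, endian = "little")
  if (length(feats) != n * d || length(coords) != n * 2L) {
    stop_pcm(sprintf("container '%s' is truncated", path), "format_error")
  }
  feature_bag(
    features = matrix(feats, nrow = n, ncol = d),
    coords = matrix(coords, nrow = n, ncol = 2L),
    slide_id = header$slide_id,
    patch_size_px = header$patch_size_px %||% 224L,
    magnification = header$magnification %||% "unknown",
    encoder_name = header$encoder_name %||% "unknown"
  )
}

#' Load container files into a cohort skeleton
#'
#' Replaces bag stubs with bags read from `<dir>/<slide_id>.bag`, enforcing a
#' single feature dimension across the cohort.
#'
#' @param cohort A `pcm_cohort` skeleton from [read_manifest()].
#' @param dir Directory holding one container per slide.
#' @return The cohort with bags loaded and `D` set.
#' @export
load_cohort_bags <- function(cohort, dir) {
  D <- NA_integer_
  cohort$patients <- lapply(cohort$patients, function(p) {
    p$bags <- lapply(p$bags, function(b) {
      if (inherits(b, "pcm_bag")) return(b)
      read_bag(file.path(dir, paste0(b$slide_id, ".bag")),
               expected_dim = if (is.na(D)) NULL else D)
    })
    for (b in p$bags) D <<- ncol(b$features)
    p
  })
  dims <- unique(unlist(lapply(cohort$patients, function(p) {
    vapply(p$bags, function(b) ncol(b$features), integer(1))
  })))
  if (length(dims) > 1L) {
    stop_pcm(sprintf("bags disagree on feature dimension: %s",
                     paste(dims, collapse = ", ")), "dimension_error")
  }
  cohort$D <- dims[1L]
  cohort
}

#' Pool all slides of a patient into one bag
#'
#' Concatenates every bag of a patient row-wise into a single (sum Ni) x D
#' matrix. Row order is bag order, then within-bag row order; provenance maps
#' each merged row back to its `(slide_id, row)` pair, a bijection used to
#' attach attention weights to tiles.
#'
#' @param record A `pcm_patient` with loaded bags.
#' @return List with `features` (matrix), `coords` (matrix), and `provenance`
#'   (tibble with columns `slide_id`, `slide_row`).
#' @export
pool_patient_bag <- function(record) {
  if (length(record$bags) < 1L) {
    stop_pcm("patient has no feature bags to pool", "validation_error")
  }
  if (!all(vapply(record$bags, inherits, logical(1), what = "pcm_bag"))) {
    stop_pcm("patient bags are not loaded (stubs present); call load_cohort_bags()",
             "validation_error")
  }
  features <- do.call(rbind, lapply(record$bags, `[[`, "features"))
  coords <- do.call(rbind, lapply(record$bags, `[[`, "coords"))
  provenance <- purrr::map_dfr(record$bags, function(b) {
    tibble::tibble(slide_id = b$slide_id, slide_row = seq_len(nrow(b$features)))
  })
  list(features = features, coords = coords, provenance = provenance)
}
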