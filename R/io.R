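#' Read a clinical cohort table
#'
#' Reads a CSV with one row per patient and validates it: `patient_id` must be
#' unique, `os_months` (overall survival, months since diagnosis) non-negative,
#' and `event` binary (1 = death observed, 0 = censored). Rows with missing OS
#' or event status are rejected and reported in the error.
#'
#' @param path Path to a CSV with columns `patient_id`, `os_months`, `event`
#'   and optionally `age_years`, `sex`, `stage` plus extra covariates.
#' @return A tibble (the cohort table).
#' @export
read_clinical_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tbl)
}

#' Validate a cohort table
#'
#' @param tbl A data frame holding the clinical columns (see
#'   [read_clinical_table()]).
#' @return The validated tibble, with `patient_id` as character.
#' @export
validate_cohort <- function(tbl) {
  required <- c("patient_id", "os_months", "event")
  missing_cols <- setdiff(required, names(tbl))
  assert_that(length(missing_cols) == 0,
              paste0("clinical table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              class = "radgen_format_error")
  tbl <- as_tibble(tbl)
  tbl$patient_id <- as.character(tbl$patient_id)
  bad <- which(is.na(tbl$os_months) | is.na(tbl$event))
  assert_that(length(bad) == 0,
              paste0("rows with missing os_months/event: ",
                     paste(tbl$patient_id[bad], collapse = ", ")),
              class = "radgen_validation_error")
  dup <- unique(tbl$patient_id[duplicated(tbl$patient_id)])
  assert_that(length(dup) == 0,
              paste0("duplicated patient_id: ", paste(dup, collapse = ", ")),
              class = "radgen_validation_error")
  assert_that(all(tbl$os_months >= 0), "os_months must be >= 0",
              class = "radgen_validation_error")
  assert_that(all(tbl$event %in% c(0, 1)), "event must be 0 or 1",
              class = "radgen_validation_error")
  tbl
}

#' Read gene-set definitions (GMT)
#'
#' Parses a standard GMT file (one gene set per line: name, description,
#' tab-separated gene symbols). The description field must carry the pathway
#' category token, either `cell_growth_and_death` or `energy_metabolism`.
#' A gene may belong to several pathways.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `pathway_id`, `display_name`, `category`,
#'   and a list-column `genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "empty GMT file", class = "radgen_format_error")
  rows <- map(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    assert_that(length(parts) >= 3,
                paste0("GMT line with no genes: ", parts[1]),
                class = "radgen_format_error")
    category <- parts[2]
    assert_that(category %in% c("cell_growth_and_death", "energy_metabolism"),
                paste0("unknown pathway category token: ", category),
                class = "radgen_format_error")
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    assert_that(length(genes) > 0,
                paste0("GMT line with empty gene list: ", parts[1]),
                class = "radgen_format_error")
    tibble(pathway_id = parts[1],
           display_name = gsub("_", " ", parts[1]),
           category = category,
           genes = list(genes))
  })
  bind_rows(rows)
}

#' Write gene sets to a GMT file
#'
#' @param pathways Pathway tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(pathways, path) {
  lines <- pmap(pathways[c("pathway_id", "category", "genes")],
                function(pathway_id, category, genes)
                  paste(c(pathway_id, category, genes), collapse = "\t"))
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read an annotated variant table
#'
#' Reads a TSV of annotated variant calls, one row per (sample, variant).
#' Columns: `sample`, `gene`, `variant_key`, `cadd_phred`, `called_by`
#' (comma-separated subset of `callerA,callerB`), `alt_reads`, `af_db1`,
#' `af_db2`, `af_db3` (population allele frequencies; blank = missing, i.e.
#' the variant is absent from that database), `clinvar` (one of `benign`,
#' `likely_benign`, `other`, `none`).
#'
#' @param path Path to the TSV.
#' @return A tibble of validated variant records.
#' @export
read_variant_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample = readr::col_character(),
                           gene = readr::col_character(),
                           variant_key = readr::col_character(),
                           cadd_phred = readr::col_character(),
                           called_by = readr::col_character(),
                           alt_reads = readr::col_integer(),
                           af_db1 = readr::col_double(),
                           af_db2 = readr::col_double(),
                           af_db3 = readr::col_double(),
                           clinvar = readr::col_character()
                         ))
  validate_variants(tbl)
}

#' Validate an annotated variant table
#'
#' @param tbl Data frame of variant records (see [read_variant_table()]).
#' @return The validated tibble with `cadd_phred` numeric.
#' @export
validate_variants <- function(tbl) {
  required <- c("sample", "gene", "variant_key", "cadd_phred", "called_by",
                "alt_reads", "af_db1", "af_db2", "af_db3", "clinvar")
  missing_cols <- setdiff(required, names(tbl))
  assert_that(length(missing_cols) == 0,
              paste0("variant table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              class = "radgen_format_error")
  tbl <- as_tibble(tbl)
  cadd <- suppressWarnings(as.numeric(tbl$cadd_phred))
  bad <- which(is.na(cadd) & !is.na(tbl$cadd_phred))
  assert_that(length(bad) == 0,
              paste0("non-numeric cadd_phred in row(s): ",
                     paste(head(bad, 5), collapse = ", ")),
              class = "radgen_validation_error")
  tbl$cadd_phred <- cadd
  assert_that(!anyNA(tbl$cadd_phred) && all(tbl$cadd_phred >= 0),
              "cadd_phred must be present and >= 0",
              class = "radgen_validation_error")
  cb <- trimws(tbl$called_by %||% "")
  assert_that(all(!is.na(cb) & nzchar(cb)),
              "called_by must be non-empty for every variant",
              class = "radgen_validation_error")
  callers <- strsplit(cb, ",", fixed = TRUE)
  assert_that(all(unlist(callers) %in% c("callerA", "callerB")),
              "called_by entries must be a subset of {callerA, callerB}",
              class = "radgen_validation_error")
  tbl$n_callers <- lengths(map(callers, unique))
  assert_that(all(tbl$alt_reads >= 0), "alt_reads must be >= 0",
              class = "radgen_validation_error")
  for (afc in c("af_db1", "af_db2", "af_db3")) {
    v <- tbl[[afc]]
    assert_that(all(is.na(v) | (v >= 0 & v <= 1)),
                paste0(afc, " must be in [0,1] or missing"),
                class = "radgen_validation_error")
  }
  tbl$clinvar[is.na(tbl$clinvar)] <- "none"
  assert_that(all(tbl$clinvar %in% c("benign", "likely_benign", "other", "none")),
              "clinvar must be one of benign, likely_benign, other, none",
              class = "radgen_validation_error")
  tbl
}

#' Write an annotated variant table to TSV
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants[, c("sample", "gene", "variant_key", "cadd_phred",
                      "called_by", "alt_reads", "af_db1", "af_db2", "af_db3",
                      "clinvar")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---- volumes -------------------------------------------------------------

#' Construct a volume-of-interest (VOI) image
#'
#' A `voi` bundles a 3D intensity grid (SUV for PET, HU for CT), a binary
#' lesion mask, an optional homogeneous reference-region mask (PET only; used
#' for SUV normalization), and the voxel spacing in mm.
#'
#' @param intensity 3D numeric array.
#' @param mask 3D logical/0-1 array, same dimensions; must be non-empty.
#' @param spacing Numeric length-3 voxel spacing (mm), all positive.
#' @param modality `"PET"` or `"CT"`.
#' @param reference Optional 3D binary reference-region mask, same dimensions.
#' @return An object of class `voi`.
#' @export
voi <- function(intensity, mask, spacing, modality = c("PET", "CT"),
                reference = NULL) {
  modality <- match.arg(modality)
  assert_that(length(dim(intensity)) == 3, "intensity must be a 3D array")
  assert_that(identical(dim(intensity), dim(mask)),
              "mask dimensions must match intensity grid")
  if (!is.null(reference)) {
    assert_that(identical(dim(intensity), dim(reference)),
                "reference mask dimensions must match intensity grid")
    reference <- array(as.logical(reference), dim = dim(reference))
  }
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be three positive values (mm)")
  mask <- array(as.logical(mask), dim = dim(mask))
  assert_that(any(mask), "lesion mask is empty: no VOI",
              class = "radgen_validation_error")
  structure(list(intensity = intensity, mask = mask, reference = reference,
                 spacing = as.numeric(spacing), modality = modality),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi %s> %s voxels @ %s mm, lesion %d voxels%s\n",
              x$modality, paste(dim(x$intensity), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), sum(x$mask),
              if (!is.null(x$reference))
                sprintf(", reference %d voxels", sum(x$reference)) else ""))
  invisible(x)
}

#' Write / read a volume as plain text
#'
#' A minimal text carrier for 3D volumes (no NIfTI dependency): a header with
#' `dims`, `spacing` and `modality`, then one voxel value per line in column-
#' major order. Masks are written as 0/1. Round-trips at full double precision.
#'
#' @param x A `voi` object.
#' @param stem Path stem; files `<stem>.img.txt`, `<stem>.mask.txt` and, when
#'   present, `<stem>.ref.txt` are written.
#' @return `stem`, invisibly.
#' @export
write_voi <- function(x, stem) {
  write_vol <- function(arr, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste("dims", paste(dim(arr), collapse = " ")),
                 paste("spacing", paste(format(x$spacing, digits = 17),
                                        collapse = " ")),
                 paste("modality", x$modality)), con)
    writeLines(format(as.vector(arr), digits = 17, trim = TRUE,
                      scientific = FALSE), con)
  }
  write_vol(x$intensity, paste0(stem, ".img.txt"))
  write_vol(x$mask + 0, paste0(stem, ".mask.txt"))
  if (!is.null(x$reference)) write_vol(x$reference + 0, paste0(stem, ".ref.txt"))
  invisible(stem)
}

read_vol <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[1], " ")[[1]][-1])
  spacing <- as.numeric(strsplit(lines[2], " ")[[1]][-1])
  modality <- strsplit(lines[3], " ")[[1]][2]
  vals <- as.numeric(lines[-(1:3)])
  assert_that(length(vals) == prod(dims), "volume payload does not match dims",
              class = "radgen_format_error")
  list(arr = array(vals, dim = dims), spacing = spacing, modality = modality)
}

#' @rdname write_voi
#' @param image_stem,mask_stem,reference_stem Path stems or full paths of the
#'   image, lesion-mask and (optional) reference-mask text volumes.
#' @export
read_voi <- function(image_stem, mask_stem = NULL, reference_stem = NULL) {
  if (is.null(mask_stem)) {
    mask_stem <- paste0(image_stem, ".mask.txt")
    reference_stem <- if (file.exists(paste0(image_stem, ".ref.txt")))
      paste0(image_stem, ".ref.txt")
    image_stem <- paste0(image_stem, ".img.txt")
  }
  img <- read_vol(image_stem)
  msk <- read_vol(mask_stem)
  assert_that(identical(dim(img$arr), dim(msk$arr)) &&
                isTRUE(all.equal(img$spacing, msk$spacing)),
              "image and mask grids differ in shape or spacing",
              class = "radgen_validation_error")
  ref <- NULL
  if (!is.null(reference_stem)) {
    r <- read_vol(reference_stem)
    assert_that(identical(dim(img$arr), dim(r$arr)),
                "reference mask grid differs from image",
                class = "radgen_validation_error")
    ref <- r$arr > 0
  }
  voi(img$arr, msk$arr > 0, img$spacing, modality = img$modality,
      reference = ref)
}
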