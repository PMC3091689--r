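#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats median mad sd rnorm rpois rbinom runif quantile cor
#'   p.adjust pt lowess approx setNames complete.cases qnorm
#' @importFrom utils head tail
NULL

# Column contracts for the plain-text interchange formats.  A "design" is a
# data.frame of section metadata (one row per array-section); a "section" is
# a bead-level table plus one design row; an "annotation" maps bead-types to
# their control category, GC content and annotation-quality flag.
.design_cols <- c("section_id", "chip_id", "sample_id", "c_uhrr",
                  "quantity_ng", "position")
.bead_cols <- c("bead_type_id", "intensity", "x", "y")
.annot_cols <- c("bead_type_id", "category", "gc_count", "is_perfect")
.categories <- c("regular", "negative", "housekeeping")

#' Construct a bead-level section
#'
#' A section bundles all bead observations of one physical array-section
#' with its design metadata (mixture proportion and starting-RNA quantity).
#' Sections are the unit of preprocessing: the two sections a WG-6 chip
#' assigns to each sample are treated as separate arrays throughout.
#'
#' @param meta One-row data.frame with columns `section_id`, `chip_id`,
#'   `sample_id`, `c_uhrr` (proportion of the hybridised mixture that is
#'   UHRR, in `[0, 1]`), `quantity_ng` (starting RNA in nanograms) and
#'   `position` (integer position on the chip).
#' @param beads data.frame with columns `bead_type_id` (non-empty strings),
#'   `intensity` (positive raw scanner intensities), `x`, `y` (coordinates).
#'   May have zero rows.
#' @return An object of class `"bead_section"`: a list with elements `meta`
#'   and `beads`.
#' @export
bead_section <- function(meta, beads) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  beads <- as.data.frame(beads, stringsAsFactors = FALSE)
  if (nrow(meta) != 1L)
    stop("'meta' must have exactly one row", call. = FALSE)
  miss <- setdiff(.design_cols, names(meta))
  if (length(miss))
    stop("'meta' lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(.bead_cols, names(beads))
  if (length(miss))
    stop("bead table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  .check_meta_row(meta)
  .check_beads(beads)
  structure(list(meta = meta[, .design_cols],
                 beads = beads[, .bead_cols]),
            class = "bead_section")
}

.check_meta_row <- function(meta) {
  if (!nzchar(meta$section_id))
    stop("section_id must be non-empty", call. = FALSE)
  if (is.na(meta$c_uhrr) || meta$c_uhrr < 0 || meta$c_uhrr > 1)
    stop("c_uhrr must lie in [0, 1], got ", meta$c_uhrr, call. = FALSE)
  if (is.na(meta$quantity_ng) || meta$quantity_ng <= 0)
    stop("quantity_ng must be positive", call. = FALSE)
  invisible(meta)
}

.check_beads <- function(beads) {
  if (!nrow(beads)) return(invisible(beads))
  if (any(!nzchar(beads$bead_type_id)))
    stop("bead_type_id must be non-empty", call. = FALSE)
  bad <- which(!is.finite(beads$intensity) | beads$intensity <= 0)
  if (length(bad))
    stop("non-positive intensity at row ", bad[1L],
         " (value ", beads$intensity[bad[1L]], ")", call. = FALSE)
  invisible(beads)
}

#' @export
print.bead_section <- function(x, ...) {
  cat(sprintf(
    "Bead-level section '%s' (chip %s, c_uhrr = %g, %g ng): %d beads, %d bead-types\n",
    x$meta$section_id, x$meta$chip_id, x$meta$c_uhrr, x$meta$quantity_ng,
    nrow(x$beads), length(unique(x$beads$bead_type_id))))
  invisible(x)
}

.sidecar_path <- function(path) sub("(\\.tsv)?$", "_meta.csv", path, perl = TRUE)

#' Read a bead-level section from disk
#'
#' Bead observations live in a tab-separated file with header columns
#' `bead_type_id`, `intensity`, `x`, `y` (one bead per row).  The section's
#' design metadata is supplied either directly via `meta` or through a
#' sidecar CSV (`<path minus .tsv>_meta.csv`) holding one design row.
#'
#' @param path Path to the bead-level TSV.
#' @param meta Optional one-row design data.frame; when `NULL` the sidecar
#'   file is read.
#' @return A [bead_section()].
#' @seealso [write_bead_level()]
#' @export
read_bead_level <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  beads <- data.table::fread(path, sep = "\t", header = TRUE,
                             colClasses = list(character = "bead_type_id"),
                             data.table = FALSE)
  miss <- setdiff(.bead_cols, names(beads))
  if (length(miss))
    stop("bead-level file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(meta)) {
    side <- .sidecar_path(path)
    if (!file.exists(side))
      stop("no metadata given and sidecar ", side, " not found", call. = FALSE)
    meta <- data.table::fread(side, header = TRUE, data.table = FALSE,
                              colClasses = list(character = c(
                                "section_id", "chip_id", "sample_id")))
  }
  bead_section(meta, beads)
}

#' Write a bead-level section to disk
#'
#' Writes the bead table as TSV and the design row as a sidecar CSV so that
#' [read_bead_level()] can restore the section without further context.
#' Missing values are written as empty fields.
#'
#' @param section A [bead_section()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bead_level <- function(section, path) {
  stopifnot(inherits(section, "bead_section"))
  data.table::fwrite(section$beads, path, sep = "\t", na = "")
  data.table::fwrite(section$meta, .sidecar_path(path), na = "")
  invisible(path)
}

#' Read a sample-sheet of section metadata
#'
#' The sample sheet is a CSV with columns `section_id`, `chip_id`,
#' `sample_id`, `c_uhrr`, `quantity_ng`, `position`.  `c_uhrr` is the
#' proportion of the hybridised mixture drawn from the UHRR source.
#'
#' @param path CSV path.
#' @return data.frame of section metadata, one row per array-section.
#' @export
read_design <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         colClasses = list(character = c(
                           "section_id", "chip_id", "sample_id")))
  miss <- setdiff(.design_cols, names(d))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d)) {
    bad <- which(is.na(d$c_uhrr) | d$c_uhrr < 0 | d$c_uhrr > 1)
    if (length(bad))
      stop("c_uhrr outside [0, 1] at row ", bad[1L],
           " (value ", d$c_uhrr[bad[1L]], ")", call. = FALSE)
    if (anyDuplicated(d$section_id))
      stop("duplicated section_id in sample sheet", call. = FALSE)
  }
  d[, .design_cols]
}

#' @rdname read_design
#' @param design data.frame of section metadata.
#' @export
write_design <- function(design, path) {
  data.table::fwrite(design[, .design_cols], path, na = "")
  invisible(path)
}

#' Read or write a bead-type annotation table
#'
#' Annotation columns: `bead_type_id`, `category` (one of `regular`,
#' `negative`, `housekeeping`), `gc_count` (GC bases of the 50-mer probe,
#' 0-50) and `is_perfect` (whether the probe has a reliable, unique,
#' full-length transcriptomic match).
#'
#' @param path CSV path.
#' @return data.frame with the four annotation columns.
#' @export
read_annotation <- function(path) {
  a <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         colClasses = list(character = c(
                           "bead_type_id", "category")))
  miss <- setdiff(.annot_cols, names(a))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(a)) {
    if (!all(a$category %in% .categories))
      stop("unknown category value(s): ",
           paste(setdiff(unique(a$category), .categories), collapse = ", "),
           call. = FALSE)
    if (any(a$gc_count < 0 | a$gc_count > 50))
      stop("gc_count must lie in [0, 50]", call. = FALSE)
    a$is_perfect <- as.logical(a$is_perfect)
  }
  a[, .annot_cols]
}

#' @rdname read_annotation
#' @param annotation data.frame with the annotation columns.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(annotation[, .annot_cols], path, na = "")
  invisible(path)
}

#' Validate a titration design against its layout constraints
#'
#' Checks the chip-pairing layout of the canonical experiment: (a) every
#' chip hosts exactly two starting quantities, each contributing the same
#' number of samples; (b) every unordered pair of quantities occurs on
#' exactly one chip; (c) each quantity-by-mixture combination occurs exactly
#' once (as one sample, i.e. two sections).  This keeps starting quantity
#' unconfounded with chip while each chip still resembles a real single- or
#' two-quantity experiment.
#'
#' @param design data.frame of section metadata as from [read_design()].
#' @return Character vector of human-readable violations; empty when the
#'   design satisfies all constraints.
#' @export
validate_design <- function(design) {
  violations <- character(0)
  if (!nrow(design)) return("design is empty")
  qs <- sort(unique(design$quantity_ng))
  nq <- length(qs)
  mixes <- sort(unique(design$c_uhrr))
  nm <- length(mixes)

  # (a) two quantities per chip, balanced samples
  per_chip <- split(design, design$chip_id)
  for (chip in names(per_chip)) {
    d <- per_chip[[chip]]
    cq <- unique(d$quantity_ng)
    if (length(cq) != 2L) {
      violations <- c(violations, sprintf(
        "chip %s hosts %d quantities (expected 2)", chip, length(cq)))
      next
    }
    n_samples <- tapply(d$sample_id, d$quantity_ng,
                        function(s) length(unique(s)))
    if (length(unique(n_samples)) != 1L)
      violations <- c(violations, sprintf(
        "chip %s has unbalanced sample counts across its quantities", chip))
  }

  # (b) each unordered quantity pair on exactly one chip
  pair_of <- vapply(per_chip, function(d) {
    cq <- sort(unique(d$quantity_ng))
    if (length(cq) == 2L) paste(cq, collapse = "|") else NA_character_
  }, character(1))
  expected_pairs <- if (nq >= 2)
    apply(utils::combn(qs, 2), 2, paste, collapse = "|") else character(0)
  for (p in expected_pairs) {
    k <- sum(pair_of == p, na.rm = TRUE)
    if (k != 1L)
      violations <- c(violations, sprintf(
        "quantity pair (%s) occurs on %d chips (expected 1)",
        gsub("\\|", ", ", p), k))
  }

  # (c) each quantity x mixture combination exactly once
  combo <- table(design$quantity_ng, design$c_uhrr)
  samples_per_combo <- tapply(
    design$sample_id, interaction(design$quantity_ng, design$c_uhrr, drop = TRUE),
    function(s) length(unique(s)))
  if (any(samples_per_combo != 1L))
    violations <- c(violations,
                    "some quantity x mixture combinations occur more than once")
  full <- expand.grid(q = qs, m = mixes)
  have <- with(design, unique(paste(quantity_ng, c_uhrr)))
  missing_combo <- setdiff(paste(full$q, full$m), have)
  if (length(missing_combo))
    violations <- c(violations, sprintf(
      "%d quantity x mixture combinations are absent", length(missing_combo)))
  violations
}

#' Bundle summarised expression matrices
#'
#' The summarised-experiment container: three aligned matrices indexed by
#' bead-type (rows) and array-section (columns) holding the mean log2
#' intensity of the retained beads, the number of beads used, and the
#' empirical detection p-value.  A bead-type absent from a section carries
#' `n_beads = 0` and `NA` mean and detection p.
#'
#' @param log2_mean,n_beads,detection_p Numeric matrices of identical shape
#'   and dimnames.
#' @return Object of class `"bead_expression"`.
#' @export
bead_expression <- function(log2_mean, n_beads, detection_p) {
  stopifnot(is.matrix(log2_mean), is.matrix(n_beads), is.matrix(detection_p))
  if (!identical(dim(log2_mean), dim(n_beads)) ||
      !identical(dim(log2_mean), dim(detection_p)))
    stop("matrices must share shape", call. = FALSE)
  if (is.null(rownames(log2_mean)) || is.null(colnames(log2_mean)))
    stop("matrices must carry bead-type rownames and section colnames",
         call. = FALSE)
  zero <- n_beads == 0
  if (any(zero & !is.na(log2_mean)))
    stop("bead-types with n_beads = 0 must have missing log2_mean",
         call. = FALSE)
  structure(list(log2_mean = log2_mean, n_beads = n_beads,
                 detection_p = detection_p),
            class = "bead_expression")
}

#' @export
print.bead_expression <- function(x, ...) {
  cat(sprintf("Summarised bead expression: %d bead-types x %d sections\n",
              nrow(x$log2_mean), ncol(x$log2_mean)))
  invisible(x)
}

#' @export
dim.bead_expression <- function(x) dim(x$log2_mean)

.write_one_matrix <- function(m, path) {
  d <- data.table::as.data.table(m, keep.rownames = "bead_type_id")
  data.table::fwrite(d, path, sep = "\t", na = "")
}

.read_one_matrix <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         colClasses = list(character = "bead_type_id"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$bead_type_id
  m
}

#' Read or write summary matrices as TSV triplets
#'
#' Three tab-separated files (`<prefix>_means.tsv`, `<prefix>_counts.tsv`,
#' `<prefix>_detection.tsv`), each bead-types by sections with a leading
#' `bead_type_id` column.
#'
#' @param prefix Path prefix for the three files.
#' @return [write_expression()] returns `prefix` invisibly;
#'   [read_expression()] a [bead_expression()].
#' @export
write_expression <- function(em, prefix) {
  stopifnot(inherits(em, "bead_expression"))
  .write_one_matrix(em$log2_mean, paste0(prefix, "_means.tsv"))
  .write_one_matrix(em$n_beads, paste0(prefix, "_counts.tsv"))
  .write_one_matrix(em$detection_p, paste0(prefix, "_detection.tsv"))
  invisible(prefix)
}

#' @rdname write_expression
#' @param em A [bead_expression()] object.
#' @export
read_expression <- function(prefix) {
  bead_expression(
    log2_mean = .read_one_matrix(paste0(prefix, "_means.tsv")),
    n_beads = .read_one_matrix(paste0(prefix, "_counts.tsv")),
    detection_p = .read_one_matrix(paste0(prefix, "_detection.tsv")))
}
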