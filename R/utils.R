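# Internal helpers shared across modules.

EROSION_LEVELS <- c("E0", "EL", "EM", "EH")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation so each generator stage can be re-run
# independently from one global seed. Kept below 2^31 - 1 (R integer range).
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L) + 1)
}

stop_stage <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

# validate a samples x OTUs count matrix
validate_otu_table <- function(counts, where = "otu_table") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_stage(where, "counts must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_stage(where, "counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    stop_stage(where, "duplicate sample identifier: %s",
               rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop_stage(where, "duplicate OTU identifier: %s",
               colnames(counts)[duplicated(colnames(counts))][1])
  if (anyNA(counts)) stop_stage(where, "counts contain missing values")
  if (any(counts < 0)) stop_stage(where, "negative counts are not allowed")
  if (any(counts != round(counts)))
    stop_stage(where, "counts must be integers")
  invisible(counts)
}

validate_metadata <- function(metadata, where = "metadata") {
  required <- c("sample_id", "site", "erosion", "transect", "plot")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0)
    stop_stage(where, "missing metadata column(s): %s",
               paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop_stage(where, "duplicate sample_id: %s",
               metadata$sample_id[duplicated(metadata$sample_id)][1])
  bad <- setdiff(unique(as.character(metadata$erosion)), EROSION_LEVELS)
  if (length(bad) > 0)
    stop_stage(where, "unknown erosion label(s): %s (expected %s)",
               paste(bad, collapse = ", "),
               paste(EROSION_LEVELS, collapse = "/"))
  key <- do.call(paste, c(metadata[c("site", "erosion", "transect", "plot")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop_stage(where, "(site, erosion, transect, plot) combinations must be unique")
  metadata$erosion <- factor(as.character(metadata$erosion),
                             levels = EROSION_LEVELS, ordered = TRUE)
  invisible(metadata)
}

SOIL_VARIABLES <- c("moisture", "pH", "OC", "TN", "TP", "NH4", "NO3",
                    "AP", "AK", "MBC", "MBN", "Cm", "Nm")

validate_soil_table <- function(soil, where = "soil_table") {
  if (!"sample_id" %in% names(soil))
    stop_stage(where, "missing sample_id column")
  missing <- setdiff(SOIL_VARIABLES, names(soil))
  if (length(missing) > 0)
    stop_stage(where, "missing soil variable column(s): %s",
               paste(missing, collapse = ", "))
  if (anyDuplicated(soil$sample_id))
    stop_stage(where, "duplicate sample_id: %s",
               soil$sample_id[duplicated(soil$sample_id)][1])
  nonneg <- setdiff(SOIL_VARIABLES, "Nm")  # net mineralized N may be negative
  for (v in nonneg) {
    if (any(soil[[v]] < 0, na.rm = TRUE))
      stop_stage(where, "negative values in %s", v)
  }
  if (any(soil$pH <= 0 | soil$pH >= 14, na.rm = TRUE))
    stop_stage(where, "pH outside (0, 14)")
  invisible(soil)
}

# Align sample identifiers across the three tables; error on mismatch.
align_samples <- function(counts, metadata, soil = NULL) {
  ids <- rownames(counts)
  if (!setequal(ids, metadata$sample_id))
    stop_stage("align", "sample ids differ between OTU table and metadata")
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  out <- list(counts = counts, metadata = metadata)
  if (!is.null(soil)) {
    if (!setequal(ids, soil$sample_id))
      stop_stage("align", "sample ids differ between OTU table and soil table")
    out$soil <- soil[match(ids, soil$sample_id), , drop = FALSE]
  }
  out
}

# Compact letter display by insert-and-absorb over a pairwise significance
# matrix (TRUE = significantly different). Groups sharing a letter are not
# significantly different.
letter_display <- function(signif_mat) {
  groups <- rownames(signif_mat)
  stopifnot(!is.null(groups), ncol(signif_mat) == nrow(signif_mat))
  cols <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !isTRUE(signif_mat[i, j])) next
      for (k in rev(seq_along(cols))) {
        col <- cols[[k]]
        if (groups[i] %in% col && groups[j] %in% col) {
          cols[[k]] <- setdiff(col, groups[i])
          cols <- append(cols, list(setdiff(col, groups[j])))
        }
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[b] &&
              all(cols[[a]] %in% cols[[b]]) &&
              (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) letters_out[g] <- paste0(letters_out[g], letters[k])
  }
  letters_out
}
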