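#' Label tables
#'
#' A label table maps parcellation label ids to region metadata: a readable
#' name, the tissue class the region belongs to (`GM`, `WM` or
#' `ventricle_CSF`), the hemisphere (`left`, `right` or `both`), and flags
#' marking cerebellar and cortical regions. The tissue class drives the
#' tissue-constrained label fusion; the cerebellum flags identify the single
#' cerebellar WM and cerebellar GM regions (atlas labels 7 and 8 in the
#' whole-brain protocol used here).
#'
#' @param label positive integer ids (unique).
#' @param name region names.
#' @param tissue_class one of `"GM"`, `"WM"`, `"ventricle_CSF"` per label.
#' @param hemisphere one of `"left"`, `"right"`, `"both"` per label.
#' @param is_cerebellum,is_cortical logical flags per label.
#' @return A tibble of class `label_table`.
#' @export
label_table <- function(label, name, tissue_class, hemisphere = "left",
                        is_cerebellum = FALSE, is_cortical = FALSE) {
  tbl <- tibble(
    label = as.integer(label),
    name = as.character(name),
    tissue_class = as.character(tissue_class),
    hemisphere = as.character(hemisphere),
    is_cerebellum = as.logical(is_cerebellum),
    is_cortical = as.logical(is_cortical)
  )
  validate_label_table(tbl)
}

validate_label_table <- function(tbl) {
  if (anyDuplicated(tbl$label)) abort("label ids must be unique")
  if (any(tbl$label <= 0L)) abort("label ids must be positive")
  if (!all(tbl$tissue_class %in% c("GM", "WM", "ventricle_CSF"))) {
    abort("tissue_class must be GM, WM or ventricle_CSF")
  }
  if (!all(tbl$hemisphere %in% c("left", "right", "both"))) {
    abort("hemisphere must be left, right or both")
  }
  cb <- tbl[tbl$is_cerebellum, ]
  if (nrow(cb) > 0) {
    if (sum(cb$tissue_class == "WM") != 1 || sum(cb$tissue_class == "GM") != 1) {
      abort("a cerebellum needs exactly one cerebellar WM and one cerebellar GM label")
    }
  }
  class(tbl) <- unique(c("label_table", class(tbl)))
  tbl
}

#' @rdname label_table
#' @param path CSV path with columns label, name, tissue_class, hemisphere,
#'   is_cerebellum, is_cortical.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  label_table(df$label, df$name, df$tissue_class, df$hemisphere,
              as.logical(df$is_cerebellum), as.logical(df$is_cortical))
}

#' @rdname label_table
#' @param table a `label_table`.
#' @export
write_label_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# id helpers -----------------------------------------------------------------

labels_of <- function(table, tissue = NULL, cerebellum = NULL, cortical = NULL,
                      hemisphere = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(tissue)) keep <- keep & table$tissue_class %in% tissue
  if (!is.null(cerebellum)) keep <- keep & table$is_cerebellum == cerebellum
  if (!is.null(cortical)) keep <- keep & table$is_cortical == cortical
  if (!is.null(hemisphere)) keep <- keep & table$hemisphere %in% hemisphere
  table$label[keep]
}

cerebellar_wm_label <- function(table) {
  ids <- labels_of(table, tissue = "WM", cerebellum = TRUE)
  if (length(ids) == 0) NA_integer_ else ids[1]
}

cerebellar_gm_label <- function(table) {
  ids <- labels_of(table, tissue = "GM", cerebellum = TRUE)
  if (length(ids) == 0) NA_integer_ else ids[1]
}

check_labels_covered <- function(vol, table) {
  present <- setdiff(unique(as.vector(vol$values)), 0L)
  missing <- setdiff(present, table$label)
  if (length(missing) > 0) {
    abort(sprintf("labels absent from the label table: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
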