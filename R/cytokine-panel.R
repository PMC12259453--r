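# CytokinePanel: samples x analytes concentration matrix with a
# not-detected mask (NA cells) and the functional-category map.

#' Construct a cytokine panel
#'
#' A cytokine panel holds a samples-by-analytes matrix of raw concentrations
#' (pg/mL). Measurements below the assay detection limit are "not detected"
#' and stored as `NA`; they are excluded from quantiles, tests and
#' correlations throughout the package.
#'
#' @param values Numeric matrix (samples in rows, analytes in columns) with
#'   row and column names. `NA` marks not-detected cells; all numeric values
#'   must be non-negative.
#' @param categories Analyte-to-category map: a data frame with columns
#'   `analyte` and `category` (default [cytokine_categories]). Every column
#'   of `values` must be covered.
#' @return An object of class `cytokine_panel`.
#' @export
cytokine_panel <- function(values, categories = cytokine_categories) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x analytes).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry sample row names and analyte column names.")
  }
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative concentration at sample '%s', analyte '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  cat_map <- category_lookup(categories)
  missing <- setdiff(colnames(values), names(cat_map))
  if (length(missing)) {
    abort(paste0("analytes missing from the category map: ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(values = values, categories = cat_map[colnames(values)]),
    class = "cytokine_panel"
  )
}

category_lookup <- function(categories) {
  if (is.data.frame(categories)) {
    setNames(as.character(categories$category), categories$analyte)
  } else if (is.character(categories) && !is.null(names(categories))) {
    categories
  } else {
    abort("`categories` must be a data frame (analyte, category) or a named character vector.")
  }
}

#' @export
print.cytokine_panel <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cytokine_panel> %d samples x %d analytes (%.1f%% not detected)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.cytokine_panel <- function(x) dim(x$values)

#' Tidy a cytokine panel into long format
#'
#' @param x A [cytokine_panel].
#' @param ... Unused.
#' @return A tibble with one row per (sample, analyte): `sample_id`,
#'   `analyte`, `category`, `concentration` (`NA` when not detected) and
#'   `detected`.
#' @exportS3Method tibble::as_tibble
as_tibble.cytokine_panel <- function(x, ...) {
  v <- x$values
  tibble(
    sample_id = rep(rownames(v), times = ncol(v)),
    analyte = rep(colnames(v), each = nrow(v)),
    category = rep(unname(x$categories), each = nrow(v)),
    concentration = as.vector(v),
    detected = !is.na(as.vector(v))
  )
}

# subset a panel to a set of samples (keeps classes and maps)
panel_subset <- function(panel, sample_ids) {
  missing <- setdiff(sample_ids, rownames(panel$values))
  if (length(missing)) {
    abort(paste0("samples not present in the panel: ", paste(missing, collapse = ", ")))
  }
  cytokine_panel(panel$values[sample_ids, , drop = FALSE],
                 categories = panel$categories)
}
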