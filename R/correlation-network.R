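# Thresholded Pearson correlation networks over preprocessed cytokine
# matrices: all-pairs correlation, BH control, |r| + FDR edge rule,
# connected components, deterministic force-directed layout, summaries.

#' All-pairs Pearson correlation of a samples x analytes matrix
#'
#' Computes the Pearson coefficient for every unordered analyte pair on
#' pairwise-complete samples, with the two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. Pairs with fewer than
#' `min_pairs` complete observations, and pairs involving a zero-variance
#' analyte, are skipped and recorded.
#'
#' @param mat Numeric matrix, samples in rows, analytes in columns
#'   (typically the output of [preprocess_cytokines()]). `NA` = not detected.
#' @param min_pairs Minimum complete observations per pair (default 4).
#' @return Tibble with columns `analyte_a`, `analyte_b` (`a < b`), `n`, `r`,
#'   `raw_p`; skipped pairs are in the `"skipped"` attribute.
#' @export
pearson_all_pairs <- function(mat, min_pairs = 4L) {
  if (!is.matrix(mat) || is.null(colnames(mat))) {
    abort("`mat` must be a matrix with analyte column names.")
  }
  m <- ncol(mat)
  if (m < 2L) abort("need at least two analytes.")
  obs <- !is.na(mat)
  npair <- crossprod(obs)
  suppressWarnings(rmat <- stats::cor(mat, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(rmat), arr.ind = TRUE)
  out <- tibble(
    analyte_a = colnames(mat)[idx[, 1]],
    analyte_b = colnames(mat)[idx[, 2]],
    n = as.integer(npair[idx]),
    r = rmat[idx]
  )
  keep <- out$n >= min_pairs & !is.na(out$r)
  skipped <- out[!keep, c("analyte_a", "analyte_b", "n")]
  skipped$reason <- ifelse(out$n[!keep] < min_pairs, "too few complete pairs",
                           "zero variance")
  out <- out[keep, ]
  tt <- out$r * sqrt((out$n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$raw_p <- 2 * stats::pt(-abs(tt), df = out$n - 2)
  attr(out, "skipped") <- skipped
  out
}

#' Build a thresholded cytokine correlation network
#'
#' Keeps an edge between two analytes iff `|r| >= r_min` and the BH-adjusted
#' p-value is below `alpha`. Analytes without any retained edge stay in the
#' network as degree-0 nodes. Clusters are the connected components of the
#' kept graph.
#'
#' @param pairs Tibble from [pearson_all_pairs()] with an `adjusted_p`
#'   column added (see [bh_adjust()]); BH is applied per correlation matrix,
#'   i.e. within one (group, compartment).
#' @param r_min Minimum absolute Pearson coefficient (default 0.6).
#' @param alpha FDR threshold (default 0.05).
#' @param categories Analyte category map (data frame or named vector).
#' @param analytes Node set; defaults to all analytes appearing in `pairs`.
#'   Pass the full column set of the input matrix to retain analytes whose
#'   pairs were all skipped.
#' @return A `cytokine_network`: list with `nodes` (analyte, category,
#'   degree, component), `edges` (analyte_a, analyte_b, r, raw_p,
#'   adjusted_p, sign), `graph` (igraph object) and `params`.
#' @export
build_network <- function(pairs, r_min = 0.6, alpha = 0.05,
                          categories = cytokine_categories, analytes = NULL) {
  need <- c("analyte_a", "analyte_b", "r", "adjusted_p")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` must carry columns analyte_a, analyte_b, r and adjusted_p (run bh_adjust() first).")
  }
  analytes <- analytes %||% sort(unique(c(pairs$analyte_a, pairs$analyte_b)))
  cat_map <- category_lookup(categories)
  missing <- setdiff(analytes, names(cat_map))
  if (length(missing)) {
    abort(paste0("analytes missing from the category map: ", paste(missing, collapse = ", ")))
  }
  edges <- pairs |>
    dplyr::filter(abs(.data$r) >= r_min, .data$adjusted_p < alpha) |>
    dplyr::mutate(
      a = pmin(.data$analyte_a, .data$analyte_b),
      b = pmax(.data$analyte_a, .data$analyte_b),
      analyte_a = .data$a, analyte_b = .data$b,
      sign = ifelse(.data$r >= 0, "+", "-")
    ) |>
    dplyr::select("analyte_a", "analyte_b", dplyr::any_of(c("n")), "r",
                  dplyr::any_of("raw_p"), "adjusted_p", "sign") |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$analyte_a, .data$analyte_b)
  g <- igraph::graph_from_data_frame(
    edges[, c("analyte_a", "analyte_b", "r", "adjusted_p", "sign")],
    directed = FALSE,
    vertices = data.frame(name = analytes,
                          category = unname(cat_map[analytes]))
  )
  comp <- igraph::components(g)
  nodes <- tibble(
    analyte = analytes,
    category = unname(cat_map[analytes]),
    degree = as.integer(igraph::degree(g)[analytes]),
    component = as.integer(comp$membership[analytes])
  )
  structure(
    list(nodes = nodes, edges = edges, graph = g,
         params = list(r_min = r_min, alpha = alpha)),
    class = "cytokine_network"
  )
}

#' @export
print.cytokine_network <- function(x, ...) {
  cat(sprintf("<cytokine_network> %d nodes, %d edges (%d +, %d -), %d components\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-"),
              length(unique(x$nodes$component))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cytokine_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.cytokine_network <- function(x, ...) {
  s <- network_summary(x)
  tibble(
    n_nodes = s$n_nodes, n_edges = s$n_edges,
    n_positive = s$n_positive, n_negative = s$n_negative,
    n_components = s$n_components,
    n_connected_nodes = s$n_connected_nodes,
    max_abs_r = if (nrow(x$edges)) max(abs(x$edges$r)) else NA_real_
  )
}

#' Deterministic force-directed network layout
#'
#' Fruchterman-Reingold layout of a cytokine network, seeded so the same
#' seed always yields the same coordinates. Edge weights are `|r|`.
#'
#' @param network A [build_network()] result.
#' @param seed Integer RNG seed.
#' @param iterations Number of layout iterations (default 200).
#' @return Tibble with `analyte`, `x`, `y` (empty when the graph is empty).
#' @export
layout_force_directed <- function(network, seed = 1L, iterations = 200L) {
  stopifnot(inherits(network, "cytokine_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0L) {
    return(tibble(analyte = character(), x = double(), y = double()))
  }
  w <- if (igraph::ecount(g) > 0L) abs(igraph::E(g)$r) else NULL
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = iterations, weights = w)
  tibble(analyte = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Summarise a cytokine correlation network
#'
#' @param network A [build_network()] result.
#' @param n_top Number of highest-degree nodes to report (default 3).
#' @return List: edge counts by sign, component count, top-degree nodes,
#'   strongest positive and negative edges, and per-category node
#'   participation (nodes with at least one edge vs all nodes).
#' @export
network_summary <- function(network, n_top = 3L) {
  stopifnot(inherits(network, "cytokine_network"))
  e <- network$edges; n <- network$nodes
  top <- n |> dplyr::arrange(dplyr::desc(.data$degree), .data$analyte) |>
    dplyr::filter(.data$degree > 0) |> head(n_top)
  strongest <- function(sgn) {
    ee <- e[e$sign == sgn, ]
    if (!nrow(ee)) return(NULL)
    ee[which.max(abs(ee$r)), ]
  }
  list(
    n_nodes = nrow(n),
    n_edges = nrow(e),
    n_positive = sum(e$sign == "+"),
    n_negative = sum(e$sign == "-"),
    n_components = length(unique(n$component)),
    n_connected_nodes = sum(n$degree > 0),
    top_degree = top,
    strongest_positive = strongest("+"),
    strongest_negative = strongest("-"),
    category_participation = n |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n_nodes = dplyr::n(),
                       n_connected = sum(.data$degree > 0),
                       .groups = "drop")
  )
}

#' Heuristic sub-cluster detection
#'
#' Greedy-modularity communities within the thresholded graph. This is a
#' heuristic refinement of the connected components (which are the
#' package's primary "cluster" notion) for exploring sub-structure; the
#' partition is not a statistical inference.
#'
#' @param network A [build_network()] result.
#' @return Tibble with `analyte` and integer `community`.
#' @export
network_communities <- function(network) {
  stopifnot(inherits(network, "cytokine_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0L) {
    return(tibble(analyte = character(), community = integer()))
  }
  cm <- igraph::cluster_fast_greedy(g, weights = if (igraph::ecount(g))
    abs(igraph::E(g)$r) else NULL)
  tibble(analyte = igraph::V(g)$name,
         community = as.integer(igraph::membership(cm)))
}
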