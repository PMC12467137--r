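#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_col geom_segment geom_text labs theme_minimal scale_colour_manual
#'   theme element_blank
#' @export
ggplot2::autoplot

#' @export
tidy.cerna_de <- function(x, ...) as_tibble(x)

#' @export
glance.cerna_de <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_up = sum(x$regulated == "up"),
         n_down = sum(x$regulated == "down"),
         n_ns = sum(x$regulated == "ns"),
         lfc_thr = attr(x, "lfc_thr"), p_thr = attr(x, "p_thr"))
}

#' @export
tidy.cerna_edges <- function(x, ...) {
  bind_rows(
    x$circ_mir |> mutate(edge_type = "circ_mir",
                         node_a = .data$circ_id, node_b = .data$mirna_id),
    x$mir_mrna |> mutate(edge_type = "mir_mrna",
                         node_a = .data$mrna_id, node_b = .data$mirna_id),
    x$circ_mrna |> mutate(edge_type = "circ_mrna",
                          node_a = .data$circ_id, node_b = .data$mrna_id)) |>
    select("edge_type", "node_a", "node_b", "method", "coefficient",
           "p_value", "n")
}

#' @export
glance.cerna_edges <- function(x, ...) {
  tibble(n_circ_mir = nrow(x$circ_mir), n_mir_mrna = nrow(x$mir_mrna),
         n_circ_mrna = nrow(x$circ_mrna))
}

#' @export
tidy.cerna_triples <- function(x, ...) as_tibble(x)

#' @export
glance.cerna_triples <- function(x, ...) {
  tibble(n_triples = nrow(x),
         n_circ = dplyr::n_distinct(x$circ_id),
         n_mirna = dplyr::n_distinct(x$mirna_id),
         n_mrna = dplyr::n_distinct(x$mrna_id))
}

#' @export
tidy.cerna_ora <- function(x, ...) as_tibble(x)

#' @export
glance.cerna_ora <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha"))
}

#' Volcano plot of differential-expression results
#'
#' @param object A `cerna_de` tibble from [call_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_de <- function(object, ...) {
  lfc_thr <- attr(object, "lfc_thr") %||% 1
  p_thr <- attr(object, "p_thr") %||% 0.05
  ggplot(as_tibble(object),
         aes(x = .data$log2fc, y = -log10(.data$p_value),
             colour = .data$regulated)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = c(-lfc_thr, lfc_thr), linetype = "dashed") +
    geom_hline(yintercept = -log10(p_thr), linetype = "dashed") +
    scale_colour_manual(values = c(up = "#d62728", down = "#1f77b4",
                                   ns = "grey60")) +
    labs(x = "log2 fold change (G vs C)", y = "-log10 p-value",
         colour = NULL) +
    theme_minimal()
}

#' Dot plot of over-representation results
#'
#' @param object A `cerna_ora` tibble.
#' @param top Number of most-enriched terms to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_ora <- function(object, top = 15, ...) {
  d <- as_tibble(object) |> head(top) |>
    mutate(term = factor(.data$term_id, levels = rev(.data$term_id)),
           gene_ratio = .data$k / .data$n)
  ggplot(d, aes(x = .data$gene_ratio, y = .data$term,
                size = .data$k, colour = -log10(.data$p_adjusted))) +
    geom_point() +
    labs(x = "gene ratio (k / n)", y = NULL, size = "hits",
         colour = "-log10 adj. p") +
    theme_minimal()
}

#' Tripartite diagram of a ceRNA network
#'
#' Nodes in three columns (circRNA, miRNA, mRNA); segment width follows the
#' absolute correlation of each leg, the standard flow layout for small ceRNA
#' networks.
#'
#' @param object A `cerna_triples` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_triples <- function(object, ...) {
  triples <- as_tibble(object)
  if (nrow(triples) == 0) {
    return(ggplot() + labs(title = "empty ceRNA network") + theme_minimal())
  }
  nodes <- sankey_nodes(triples) |>
    mutate(x = dplyr::recode(.data$column, circRNA = 1, miRNA = 2, mRNA = 3)) |>
    group_by(.data$column) |>
    mutate(y = (row_number() - 1) / pmax(n() - 1, 1)) |>
    ungroup()
  links <- sankey_links(triples) |>
    left_join(nodes |> select("name", xs = "x", ys = "y"),
              by = c(source = "name")) |>
    left_join(nodes |> select("name", xe = "x", ye = "y"),
              by = c(target = "name"))
  ggplot() +
    geom_segment(data = links,
                 aes(x = .data$xs, y = .data$ys, xend = .data$xe,
                     yend = .data$ye, linewidth = .data$weight),
                 colour = "grey55", alpha = 0.6) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y), size = 2) +
    geom_text(data = nodes, aes(x = .data$x, y = .data$y, label = .data$name),
              vjust = -0.8, size = 2.8) +
    labs(x = NULL, y = NULL, linewidth = "|correlation|") +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}

#' Bar plot of circRNA type composition
#'
#' @param calls A `circ_calls` tibble with a `circ_type` column.
#' @return A ggplot object.
#' @export
plot_circ_types <- function(calls) {
  stopifnot("circ_type" %in% names(calls))
  d <- as_tibble(calls) |> dplyr::count(.data$circ_type)
  ggplot(d, aes(x = stats::reorder(.data$circ_type, -.data$n), y = .data$n)) +
    geom_col(fill = "#1f77b4") +
    labs(x = NULL, y = "circRNA calls") +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
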