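available_targets <- function(result) {
  unique(c(paste0(result$ligand, "->", result$receptor), result$pathway))
}

result_target <- function(result, target) {
  hit <- dplyr::filter(
    result,
    paste0(.data$ligand, "->", .data$receptor) == target |
      .data$ligand == paste0("pathway:", target) |
      (.data$pathway == target & startsWith(.data$ligand, "pathway:"))
  )
  if (nrow(hit) == 0) {
    abort(sprintf("target '%s' not found. Available: %s", target,
                  paste(available_targets(result), collapse = ", ")))
  }
  hit
}

#' Communication strength matrix for one target
#'
#' Extracts the G x G matrix of estimated communication strengths
#' (sender types as rows, receiver types as columns) for one
#' ligand-receptor pair (`"LIG->REC"`) or pathway label, masking cells whose
#' adjusted p-value exceeds the significance threshold as `NA`.
#'
#' @param result A `ccc_result` from [infer_ccc()] or [infer_ccc_pathway()].
#' @param target Pair id (`"ligand->receptor"`) or pathway label.
#' @param threshold Significance threshold on the adjusted p-value.
#' @return Numeric matrix with type-name dimnames.
#' @export
ccc_matrix <- function(result, target, threshold = 0.1) {
  rows <- result_target(result, target)
  types <- sort(unique(c(rows$sender_type, rows$receiver_type)))
  m <- matrix(NA_real_, length(types), length(types),
              dimnames = list(sender = types, receiver = types))
  sig <- !is.na(rows$p_adjusted) & rows$p_adjusted <= threshold
  if (!any(sig)) warn(sprintf("no significant cell for target '%s'.", target))
  keep <- rows[sig, ]
  m[cbind(keep$sender_type, keep$receiver_type)] <- keep$estimate
  m
}

#' Heatmap of communication strengths
#'
#' Tile heatmap of the signed communication strengths of one target, with
#' non-significant cells masked (grey). Sender types on rows, receiver types
#' on columns.
#'
#' @inheritParams ccc_matrix
#' @return A ggplot object.
#' @export
plot_ccc_heatmap <- function(result, target, threshold = 0.1) {
  m <- ccc_matrix(result, target, threshold)
  df <- tibble::tibble(
    sender = rep(rownames(m), times = ncol(m)),
    receiver = rep(colnames(m), each = nrow(m)),
    estimate = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$receiver, y = .data$sender,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(title = target, x = "receiver type", y = "sender type",
                  fill = "strength") +
    ggplot2::theme_minimal()
}

#' Significant communication edges for one target
#'
#' Machine-readable edge list backing the network plot: one row per
#' significant (sender, receiver) coefficient with its sign and a width
#' proportional to the absolute estimate (max width 1).
#'
#' @inheritParams ccc_matrix
#' @return Tibble with sender, receiver, estimate, sign, width.
#' @export
ccc_edges <- function(result, target, threshold = 0.1) {
  rows <- result_target(result, target)
  sig <- dplyr::filter(rows, !is.na(.data$p_adjusted),
                       .data$p_adjusted <= threshold)
  dplyr::transmute(
    sig, sender = .data$sender_type, receiver = .data$receiver_type,
    estimate = .data$estimate,
    sign = ifelse(.data$estimate > 0, "positive", "negative"),
    width = abs(.data$estimate) / max(abs(.data$estimate))
  )
}

#' Communication network plot
#'
#' Directed network over cell types for one target: solid edges for positive
#' communication strengths, dashed for negative, edge width proportional to
#' the absolute estimate; node positions on a fixed circle (alphabetical
#' order) so renderings are reproducible. Self loops (autocrine) are drawn
#' as small circles above the node.
#'
#' @inheritParams ccc_matrix
#' @return A ggplot object.
#' @export
plot_ccc_network <- function(result, target, threshold = 0.1) {
  rows <- result_target(result, target)
  types <- sort(unique(c(rows$sender_type, rows$receiver_type)))
  ang <- seq(0, 2 * pi, length.out = length(types) + 1)[seq_along(types)]
  nodes <- tibble::tibble(type = types, x = cos(ang), y = sin(ang))
  edges <- ccc_edges(result, target, threshold)
  if (nrow(edges) == 0) warn(sprintf("no significant edge for target '%s'.", target))
  edges <- dplyr::left_join(edges, nodes, by = c(sender = "type"))
  edges <- dplyr::left_join(edges, nodes, by = c(receiver = "type"),
                            suffix = c("", "_to"))
  loops <- dplyr::filter(edges, .data$sender == .data$receiver)
  arcs <- dplyr::filter(edges, .data$sender != .data$receiver)
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 8, color = "grey30") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.25, .data$y * 1.25,
                                    label = .data$type)) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::labs(title = target) +
    ggplot2::theme_void()
  if (nrow(arcs) > 0) {
    p <- p + ggplot2::geom_curve(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linetype = .data$sign,
                   linewidth = .data$width),
      curvature = 0.15, color = "grey40",
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"))
    )
  }
  if (nrow(loops) > 0) {
    p <- p + ggplot2::geom_point(
      data = loops,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                   size = .data$width, shape = .data$sign),
      color = "grey40"
    ) + ggplot2::scale_shape_manual(values = c(positive = 16, negative = 1))
  }
  p + ggplot2::scale_linetype_manual(
        values = c(positive = "solid", negative = "dashed")) +
    ggplot2::scale_linewidth(range = c(0.3, 2), limits = c(0, 1))
}

#' Plot method for communication result tables
#'
#' Dispatches to [plot_ccc_heatmap()] or [plot_ccc_network()].
#'
#' @param object A `ccc_result`.
#' @param target Pair id or pathway label; defaults to the first pair.
#' @param threshold Adjusted-p significance threshold.
#' @param kind `"heatmap"` or `"network"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ccc_result <- function(object, target = NULL, threshold = 0.1,
                                kind = c("heatmap", "network"), ...) {
  kind <- match.arg(kind)
  target <- target %||% paste0(object$ligand[1], "->", object$receptor[1])
  switch(kind,
    heatmap = plot_ccc_heatmap(object, target, threshold),
    network = plot_ccc_network(object, target, threshold)
  )
}
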