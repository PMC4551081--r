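#' Edge list of a fitted connectivity map
#'
#' One row per freed connection: source, target, lag (0 =
#' contemporaneous), type (\code{roi} for ROI-to-ROI, \code{direct} for
#' input effects, \code{modulating} for bilinear terms), level
#' (\code{group} when the connection is in the attached group mask,
#' else \code{individual}), estimate, SE and 95\% CI.
#'
#' @param model a \code{"usem"} fit.
#' @param group_spec optional group \code{\link{model_spec}} overriding
#'   \code{model$base} for the level column.
#' @return a data.frame.
#' @export
edge_list <- function(model, group_spec = model$base) {
  tab <- model$params$table
  labels <- model$spec$labels
  if (nrow(tab) == 0)
    return(data.frame(source = character(0), target = character(0),
                      lag = integer(0), type = character(0),
                      level = character(0), estimate = numeric(0),
                      se = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  src <- ifelse(tab$matrix == "gamma", paste0("u", tab$col), labels[tab$col])
  type <- c(A = "roi", Phi = "roi", gamma = "direct",
            tau = "modulating")[tab$matrix]
  level <- if (is.null(group_spec)) rep("individual", nrow(tab)) else
    ifelse(vapply(seq_len(nrow(tab)), function(i)
      isTRUE(spec_get(group_spec, tab[i, ])), NA),
      "group", "individual")
  data.frame(source = src, target = labels[tab$row], lag = tab$lag,
             type = unname(type), level = level,
             estimate = tab$estimate, se = tab$se,
             ci_low = tab$ci_low, ci_high = tab$ci_high)
}

.map_igraph <- function(el, labels) {
  verts <- unique(c(labels, el$source, el$target))
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' Export a connectivity map as a graph file
#'
#' Writes the fitted map as an edge-list CSV (the canonical
#' interchange), DOT, or GraphML graph with nodes = ROIs and edges
#' annotated by lag, type, level and weight.
#'
#' @param model a \code{"usem"} fit.
#' @param path output file.
#' @param format \code{"edgelist"}, \code{"dot"} or \code{"graphml"}.
#' @return the path, invisibly.
#' @export
export_map <- function(model, path, format = c("edgelist", "dot", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format: ", format[1]))
  el <- edge_list(model)
  if (format == "edgelist") {
    write.table(el, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    g <- .map_igraph(el, model$spec$labels)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Rebuild a model mask from an exported edge list
#'
#' Inverse of the edge-list export: reconstructs the free-parameter
#' mask (a \code{\link{model_spec}}) from the CSV.
#'
#' @param path edge-list CSV written by \code{\link{export_map}}.
#' @param labels ROI labels fixing the variable order.
#' @param n_u number of inputs in the original model.
#' @param f,g,h input lag bounds of the original model.
#' @return a \code{\link{model_spec}}.
#' @export
read_edge_list <- function(path, labels, n_u = 0, f = 1, g = 1, h = 1) {
  el <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  p <- length(labels)
  order <- max(c(el$lag[el$type == "roi"], 1))
  spec <- model_spec(p, order, labels, n_u = n_u, f = f, g = g, h = h,
                     bilinear = n_u == 1)
  for (i in seq_len(nrow(el))) {
    row <- match(el$target[i], labels)
    if (el$type[i] == "roi") {
      col <- match(el$source[i], labels)
      par <- if (el$lag[i] == 0)
        list(matrix = "A", q = NA, r = NA, row = row, col = col)
      else list(matrix = "Phi", q = el$lag[i], r = NA, row = row, col = col)
    } else if (el$type[i] == "direct") {
      col <- as.integer(sub("^u", "", el$source[i]))
      par <- list(matrix = "gamma", q = NA, r = el$lag[i], row = row,
                  col = col)
    } else {
      col <- match(el$source[i], labels)
      par <- list(matrix = "tau", q = el$lag[i], r = 1, row = row, col = col)
    }
    spec <- spec_set(spec, par, TRUE)
  }
  spec
}

#' Serialize a fitted model to JSON
#'
#' Writes every parameter (matrix name, lag, row, col, free/fixed,
#' estimate, SE, CI) plus the fit indices.
#'
#' @param model a \code{"usem"} fit.
#' @param path output file.
#' @export
model_to_json <- function(model, path) {
  tab <- param_table(model$spec)
  est <- model$params$table
  tab <- merge(tab, est[, c("id", "estimate", "se", "ci_low", "ci_high")],
               by = "id", all.x = TRUE, sort = FALSE)
  tab$estimate[is.na(tab$estimate)] <- 0
  jsonlite::write_json(
    list(kind = if (!is.null(model$input)) "eusem" else "usem",
         order = model$spec$order,
         labels = model$spec$labels,
         psi = model$params$psi,
         parameters = tab,
         fit = model$fit[c("chi2", "df", "p_value", "rmsea", "srmr",
                           "cfi", "nnfi", "converged", "n_eff")]),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize a GIMME fit to JSON + per-subject edge lists
#'
#' @param gm a \code{\link{gimme}} fit.
#' @param dir output directory (created if needed).
#' @export
gimme_to_json <- function(gm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gtab <- param_table(gm$group_spec)
  jsonlite::write_json(
    list(group_connections = gtab$id[gtab$free],
         subjects = gm$subject_ids),
    file.path(dir, "group_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in gm$subject_ids) {
    el <- edge_list(gm$fits[[id]], group_spec = gm$group_spec)
    write.table(el, file.path(dir, paste0(id, "_edges.csv")),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
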