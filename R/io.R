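#' Read a network file
#'
#' Reads an association network without sanitizing it: negative weights and
#' self-loops are kept so that their removal is a separate, logged step
#' ([sanitizeNetwork()]).
#'
#' Supported formats:
#' \describe{
#'   \item{`edge_list`}{3-column TSV `source <TAB> target <TAB> weight`;
#'     header optional (auto-detected from a non-numeric third field).
#'     Edges are undirected: `(a, b)` and `(b, a)` are the same edge and
#'     conflicting duplicate weights are an error.}
#'   \item{`adjacency`}{square CSV with taxon labels as both rownames and
#'     header; must be symmetric within 1e-9 (asymmetry is an error naming
#'     the offending cell pair); the diagonal is ignored; nonzero cells
#'     become edges.}
#'   \item{`graphml`}{GraphML as written by igraph; the `weight` edge
#'     attribute is used when present, otherwise 1.}
#' }
#'
#' @param path file to read.
#' @param format one of `"edge_list"`, `"adjacency"`, `"graphml"`.
#' @return A [RawNetwork-class]. An empty file yields an empty network with
#'   a warning.
#' @export
readNetwork <- function(path, format = c("edge_list", "adjacency",
                                         "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         edge_list = .readEdgeList(path),
         adjacency = .readAdjacency(path),
         graphml = .readGraphml(path))
}

.readEdgeList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty network file: ", path)
    return(RawNetwork(data.frame(from = character(), to = character(),
                                 weight = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("edge list must have 3 tab-separated columns; line ",
         which(nf != 3L)[1L], " has ", nf[nf != 3L][1L])
  hasHeader <- is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))
  if (hasHeader) fields <- fields[-1L]
  if (length(fields) == 0L) {
    warning("empty network file (header only): ", path)
    return(RawNetwork(data.frame(from = character(), to = character(),
                                 weight = numeric())))
  }
  m <- do.call(rbind, fields)
  w <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(w))
    stop("non-numeric edge weight on data line ", which(is.na(w))[1L])
  RawNetwork(data.frame(from = m[, 1L], to = m[, 2L], weight = w,
                        stringsAsFactors = FALSE))
}

.readAdjacency <- function(path, tol = 1e-9) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) == 0L) {
    warning("empty network file: ", path)
    return(RawNetwork(data.frame(from = character(), to = character(),
                                 weight = numeric())))
  }
  if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m)))
    stop("adjacency matrix must be square with matching row/column labels")
  m <- m[, rownames(m), drop = FALSE]
  asym <- which(abs(m - t(m)) > tol, arr.ind = TRUE)
  if (nrow(asym)) {
    i <- asym[1L, 1L]; j <- asym[1L, 2L]
    stop(sprintf(
      "adjacency matrix not symmetric: cell (%s, %s) = %g but (%s, %s) = %g",
      rownames(m)[i], colnames(m)[j], m[i, j],
      rownames(m)[j], colnames(m)[i], m[j, i]))
  }
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[ut[, 1L]],
                      to = colnames(m)[ut[, 2L]],
                      weight = m[ut], stringsAsFactors = FALSE)
  RawNetwork(edges, taxa = rownames(m))
}

.readGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) nm <- paste0("v", seq_len(igraph::vcount(g)))
  e <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- rep(1, nrow(e))
  if (nrow(e) == 0L) warning("network file has no edges: ", path)
  RawNetwork(data.frame(from = nm[e[, 1L]], to = nm[e[, 2L]], weight = w,
                        stringsAsFactors = FALSE), taxa = nm)
}

#' Write a network file
#'
#' Counterpart of [readNetwork()]; round-trip stable to 1e-9.
#'
#' @param net a [RawNetwork-class] or [AssociationNetwork-class].
#' @param path output file.
#' @param format one of `"edge_list"`, `"adjacency"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("edge_list", "adjacency",
                                               "graphml")) {
  format <- match.arg(format)
  e <- edgeTable(net)
  tx <- taxa(net)
  if (format == "edge_list") {
    utils::write.table(
      data.frame(source = e$from, target = e$to, weight = e$weight),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "adjacency") {
    m <- matrix(0, length(tx), length(tx), dimnames = list(tx, tx))
    m[cbind(e$from, e$to)] <- e$weight
    m[cbind(e$to, e$from)] <- e$weight
    utils::write.csv(as.data.frame(m), path)
  } else {
    g <- .asIgraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a binary function table
#'
#' TSV with a header of layer names and the taxon id in the first column.
#' Every cell must be 0 or 1; anything else is an error naming the cell.
#'
#' @param path file to read.
#' @return A [FunctionTable-class].
#' @export
readFunctionTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("function table needs a taxon column plus at least one layer")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate taxon ids in function table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary value in function table at taxon '%s', layer '%s'",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  FunctionTable(m)
}

#' Write a function table
#'
#' @param functions a [FunctionTable-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeFunctionTable <- function(functions, path) {
  v <- functions@values
  df <- data.frame(taxon = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a layer configuration
#'
#' YAML (or flat key-value YAML) with per-layer weights and redundancy
#' parameters plus the global balance parameters. Two spellings are
#' accepted:
#' \preformatted{
#' alpha:            # nested
#'   nitrogen_fixation: 1
#'   pathogenicity: -1
#' beta:
#'   nitrogen_fixation: 2
#'   pathogenicity: 1
#' gamma: 1
#' delta: 0
#' }
#' or flat keys `alpha.<layer>`, `beta.<layer>`, `gamma`, `delta`.
#' Missing `beta` entries default to 1; `gamma` defaults to 1 and `delta`
#' to 0 (the convention used throughout the worked analyses).
#'
#' @param path YAML file.
#' @return A [LayerConfig-class].
#' @export
readLayerConfig <- function(path) {
  y <- yaml::read_yaml(path)
  flatKeys <- grep("^(alpha|beta)\\.", names(y), value = TRUE)
  if (length(flatKeys)) {
    extra <- list()
    for (key in flatKeys) {
      p <- strsplit(key, ".", fixed = TRUE)[[1L]]
      extra[[p[1L]]][[paste(p[-1L], collapse = ".")]] <- y[[key]]
    }
    y <- y[setdiff(names(y), flatKeys)]
    for (key in names(extra)) y[[key]] <- c(y[[key]], extra[[key]])
  }
  if (is.null(y$alpha) || length(y$alpha) == 0L)
    stop("layer config must define alpha.<layer> weights")
  alpha <- unlist(y$alpha)
  layers <- names(alpha)
  beta <- rep(1, length(layers))
  names(beta) <- layers
  if (!is.null(y$beta)) {
    b <- unlist(y$beta)
    unknown <- setdiff(names(b), layers)
    if (length(unknown))
      stop("beta given for unknown layer(s): ",
           paste(unknown, collapse = ", "))
    beta[names(b)] <- b
  }
  LayerConfig(alpha = alpha, beta = beta,
              gamma = if (is.null(y$gamma)) 1 else y$gamma,
              delta = if (is.null(y$delta)) 0 else y$delta)
}

#' Write a layer configuration
#'
#' @param config a [LayerConfig-class].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeLayerConfig <- function(config, path) {
  y <- list(alpha = as.list(alphaWeights(config)),
            beta = as.list(betaWeights(config)),
            gamma = balanceGamma(config),
            delta = balanceDelta(config))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a taxon-by-sample abundance table
#'
#' TSV with sample ids in the header and the taxon id in the first column;
#' entries are non-negative read counts.
#'
#' @param path file to read.
#' @return Numeric matrix, taxa in rows.
#' @export
readAbundanceTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m) || any(m < 0)) stop("abundance table must be non-negative")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (anyDuplicated(ids)) stop("duplicate taxon ids")
  m
}

#' Write an abundance table
#'
#' @param abundance taxa x samples matrix.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(abundance, path) {
  df <- data.frame(taxon = rownames(abundance), abundance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample condition labels
#'
#' Two-column TSV `sample <TAB> condition` with a header.
#'
#' @param path file to read.
#' @return Named character vector, sample -> condition.
#' @export
readConditionLabels <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("condition file needs columns sample, condition")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample ids in condition file")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write sample condition labels
#'
#' @param conditions named character vector, sample -> condition.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeConditionLabels <- function(conditions, path) {
  utils::write.table(
    data.frame(sample = names(conditions), condition = unname(conditions)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn filterPrevalence matrix method: keeps taxa with nonzero
#'   counts in at least `minSamples` samples; the sample set is unchanged.
#'   Idempotent, and monotone in `minSamples`.
#' @export
setMethod("filterPrevalence", "matrix", function(abundance, minSamples) {
  if (length(minSamples) != 1L || is.na(minSamples) || minSamples < 0)
    stop("minSamples must be a single integer >= 0")
  keep <- rowSums(abundance > 0) >= minSamples
  abundance[keep, , drop = FALSE]
})

#' @describeIn filterPrevalence SummarizedExperiment method: filters rows
#'   by prevalence in the first assay.
#' @export
setMethod("filterPrevalence", "SummarizedExperiment",
          function(abundance, minSamples) {
  if (length(minSamples) != 1L || is.na(minSamples) || minSamples < 0)
    stop("minSamples must be a single integer >= 0")
  keep <- rowSums(SummarizedExperiment::assay(abundance) > 0) >= minSamples
  abundance[keep, ]
})

#' Write a score table
#'
#' TSV with columns `module`, `taxon`, `T`, `TP`, `TPB`, `C_func`, in the
#' canonical order (module ascending, `C_func` descending, ties by taxon
#' id). Round-trip stable to 1e-9 via [readScoreTable()].
#'
#' @param scores a [ScoreTable-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  utils::write.table(scores@scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [writeScoreTable()]
#'
#' @param path TSV file.
#' @return A [ScoreTable-class].
#' @export
readScoreTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ScoreTable(df)
}

#' Write a specificity table
#'
#' @param spec a [SpecificityTable-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeSpecificityTable <- function(spec, path) {
  utils::write.table(spec@scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a module condition-score report
#'
#' TSV with columns `module`, `condition`, `s_module`, `size`, sorted by
#' module then condition.
#'
#' @param report data.frame from [moduleConditionScores()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeModuleReport <- function(report, path) {
  report <- report[order(report$module, report$condition), , drop = FALSE]
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a module report written by [writeModuleReport()]
#'
#' @param path TSV file.
#' @return data.frame with columns `module`, `condition`, `s_module`,
#'   `size`.
#' @export
readModuleReport <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a core set
#'
#' Writes the member table as TSV and, alongside it, a JSON metadata file
#' (`<path>.json`) with the module, rule and rule diagnostics.
#'
#' @param coreSet a [CoreSet-class].
#' @param path output TSV; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeCoreSet <- function(coreSet, path) {
  utils::write.table(as.data.frame(coreSet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(list(module = coreSet@module, rule = coreSet@rule,
                 size = length(coreSet@taxa)), coreSet@parameters)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
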