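#' Read a collection of graphs from files
#'
#' Reads \code{m} graphs on a common vertex set from a directory, a vector
#' of file paths, or a JSON manifest (as written by [write_graphs()]).
#' Supported formats: whitespace-delimited edge lists (two columns, optional
#' third weight column), dense CSV adjacency matrices, and Matrix Market
#' coordinate files.  Edges stored once are symmetrized; self-loops are
#' dropped with a warning; vertex identifiers are mapped to dense indices
#' through a stable sorted dictionary shared by all graphs.
#'
#' @param path directory, character vector of files, or a \code{.json}
#'   manifest path.
#' @param format \code{"edgelist"}, \code{"dense-csv"} or
#'   \code{"matrix-market"}; ignored when a manifest provides it.
#' @param n number of vertices; required for edge lists whose files do not
#'   mention every vertex (isolated vertices), otherwise inferred.
#' @param weighted keep edge weights (default \code{FALSE}: any weight
#'   column is ignored with a warning and edges are binary).
#' @return A \code{"graph_sample"}.
#' @export
read_graphs <- function(path, format = c("edgelist", "dense-csv",
                                         "matrix-market"),
                        n = NULL, weighted = FALSE) {
  format <- match.arg(format)
  labels <- NULL
  if (length(path) == 1 && dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(edgelist|txt|csv|mtx)$"))
    if (length(files) == 0) stop("no graph files found in ", path)
  } else if (length(path) == 1 && grepl("\\.json$", path)) {
    man <- jsonlite::read_json(path, simplifyVector = TRUE)
    files <- file.path(dirname(path), man$files)
    format <- man$format
    if (!is.null(man$n)) n <- man$n
    labels <- man$labels
  } else {
    files <- path
  }
  miss <- files[!file.exists(files)]
  if (length(miss)) stop("missing graph files: ", paste(miss, collapse = ", "))

  if (format == "edgelist") {
    parsed <- lapply(files, .parse_edgelist)
    ids <- sort(unique(unlist(lapply(parsed, function(e)
      c(e$from, e$to)))))
    if (!is.null(n)) {
      if (length(ids) > n) stop("more vertex ids than n")
      if (all(grepl("^[0-9]+$", ids))) {
        num <- as.numeric(ids)
        ids <- as.character(if (min(num) == 0) 0:(n - 1) else 1:n)
      } else if (length(ids) < n) {
        stop("non-numeric vertex ids cannot be padded to n vertices")
      }
    }
    lookup <- stats::setNames(seq_along(ids), ids)
    A <- lapply(parsed, function(e) {
      Ai <- matrix(0, length(ids), length(ids))
      if (length(e$from)) {
        i <- lookup[e$from]; j <- lookup[e$to]
        w <- if (weighted) e$w else 1
        Ai[cbind(i, j)] <- w
        Ai[cbind(j, i)] <- w
      }
      if (!weighted) Ai[Ai > 0] <- 1
      Ai
    })
    if (!weighted && any(vapply(parsed, function(e) e$had_weights, FALSE)))
      warning("edge weights present but binary mode requested; weights ignored")
    return(graph_sample(A, vertex_ids = ids, labels = labels))
  }

  A <- lapply(files, function(f) {
    Ai <- if (format == "dense-csv") {
      as.matrix(utils::read.csv(f, header = FALSE))
    } else {
      as.matrix(Matrix::readMM(f))
    }
    dimnames(Ai) <- NULL
    if (nrow(Ai) != ncol(Ai)) stop("non-square adjacency matrix in ", f)
    if (max(abs(Ai - t(Ai))) > 0) Ai <- pmax(Ai, t(Ai))  # stored one triangle
    if (any(diag(Ai) != 0)) {
      warning("self-loops dropped in ", basename(f))
      diag(Ai) <- 0
    }
    if (!weighted) Ai[Ai > 0] <- 1
    Ai
  })
  sizes <- vapply(A, nrow, 0L)
  if (length(unique(sizes)) != 1)
    stop("graphs have inconsistent vertex sets: sizes ",
         paste(unique(sizes), collapse = ", "))
  graph_sample(A, labels = labels)
}

.parse_edgelist <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nums <- which(keep)
  bad <- which(vapply(toks, length, 0L) < 2)
  if (length(bad))
    stop(sprintf("malformed lines in %s: %s", file,
                 paste(nums[bad], collapse = ", ")))
  from <- vapply(toks, `[[`, "", 1)
  to <- vapply(toks, `[[`, "", 2)
  had_weights <- any(vapply(toks, length, 0L) >= 3)
  w <- vapply(toks, function(x) if (length(x) >= 3) as.numeric(x[3]) else 1, 0)
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("%d self-loop(s) dropped in %s", sum(loops), file))
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
  }
  list(from = from, to = to, w = w, had_weights = had_weights)
}

#' Write a collection of graphs to files
#'
#' Writes each graph of a sample to its own file plus a JSON manifest
#' (\code{manifest.json}) recording the format, vertex count, vertex ids,
#' file names, per-graph labels and any provenance fields supplied (for
#' instance the seed that generated a simulation).
#'
#' @param sample a \code{"graph_sample"}.
#' @param out_dir output directory (created if needed).
#' @param format \code{"edgelist"} or \code{"matrix-market"}.
#' @param provenance named list merged into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_graphs <- function(sample, out_dir,
                         format = c("edgelist", "matrix-market"),
                         provenance = list()) {
  format <- match.arg(format)
  stopifnot(inherits(sample, "graph_sample"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edgelist") "edgelist" else "mtx"
  files <- sprintf("graph-%03d.%s", seq_len(sample$m), ext)
  for (i in seq_len(sample$m)) {
    A <- sample$A[[i]]
    f <- file.path(out_dir, files[i])
    if (format == "edgelist") {
      idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
      utils::write.table(
        data.frame(from = sample$vertex_ids[idx[, 1]],
                   to = sample$vertex_ids[idx[, 2]]),
        f, row.names = FALSE, col.names = FALSE, quote = FALSE)
    } else {
      Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                              "symmetricMatrix"), "TsparseMatrix"), f)
    }
  }
  man <- c(list(format = format, n = sample$n, m = sample$m,
                vertex_ids = sample$vertex_ids, files = files,
                labels = sample$labels),
           provenance)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(man_path)
}

#' Serialize a fitted model to plain-text files
#'
#' Writes the subspace basis \code{V} as a dense CSV, the score matrices as
#' one row-stacked CSV (\code{m * d} rows), the joint singular values as
#' CSV, and a JSON record with dimensions, variant, seeds and package
#' version.
#'
#' @param fit a \code{"mase"} fit.
#' @param out_dir output directory.
#' @param provenance named list merged into the JSON record (e.g. seeds).
#' @return Invisibly, \code{out_dir}.
#' @seealso [read_fit()]
#' @export
write_fit <- function(fit, out_dir, provenance = list()) {
  stopifnot(inherits(fit, "mase"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$V, file.path(out_dir, "V.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(do.call(rbind, fit$R), file.path(out_dir, "R.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(fit$joint_singular_values,
                     file.path(out_dir, "singular_values.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- c(list(n = fit$n, m = fit$m, d = fit$d, d_i = fit$d_i,
                 variant = fit$variant,
                 package_version = as.character(utils::packageVersion("cosie")),
                 r_version = as.character(getRversion())),
            provenance)
  jsonlite::write_json(meta, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read back a serialized fit
#'
#' @param dir directory written by [write_fit()].
#' @return A \code{"mase"} object (without the original graphs).
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  V <- as.matrix(utils::read.csv(file.path(dir, "V.csv"), header = FALSE))
  dimnames(V) <- NULL
  Rstack <- as.matrix(utils::read.csv(file.path(dir, "R.csv"), header = FALSE))
  d <- meta$d
  R <- lapply(seq_len(meta$m), function(i)
    unname(Rstack[((i - 1) * d + 1):(i * d), , drop = FALSE]))
  sv <- as.numeric(utils::read.csv(file.path(dir, "singular_values.csv"),
                                   header = FALSE)[[1]])
  structure(list(V = V, R = R, d = d, d_i = meta$d_i, variant = meta$variant,
                 joint_singular_values = sv, n = meta$n, m = meta$m,
                 graphs = NULL),
            class = "mase")
}
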