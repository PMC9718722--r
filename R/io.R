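#' Read and write MHN parameter matrices
#'
#' Supported formats, chosen by file extension: CSV (`.csv`), TSV (`.tsv`,
#' `.txt`) with `d` rows by `d` columns and an optional header row, and
#' JSON (`.json`) with fields `d` and `theta` (list of rows). Shape,
#' negativity and non-numeric cells are validated on read with the
#' offending location named.
#'
#' @param path file path.
#' @param theta a `d x d` nonnegative matrix.
#' @return `read_theta` returns the validated matrix; `write_theta` returns
#'   `path` invisibly.
#' @export
read_theta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.null(obj$theta)) stop("JSON theta file needs a 'theta' field")
    m <- as.matrix(obj$theta)
    if (!is.null(obj$d) && (nrow(m) != obj$d || ncol(m) != obj$d))
      stop("declared d = ", obj$d, " does not match a ",
           nrow(m), " x ", ncol(m), " theta table")
  } else {
    sep <- if (ext == "csv") "," else "\t"
    first <- utils::read.table(path, sep = sep, nrows = 1L,
                               colClasses = "character")
    header <- anyNA(suppressWarnings(as.numeric(unlist(first))))
    tab <- utils::read.table(path, sep = sep, header = header)
    bad <- which(!vapply(tab, is.numeric, logical(1L)))
    if (length(bad))
      stop("non-numeric entries in column ", bad[1L], " of ", path)
    m <- as.matrix(tab)
  }
  theta_matrix(m)
}

#' @rdname read_theta
#' @export
write_theta <- function(theta, path) {
  theta <- theta_matrix(theta)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(d = nrow(theta), theta = theta), path,
                         auto_unbox = TRUE, digits = I(17))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    txt <- matrix(sprintf("%.17g", theta), nrow(theta))
    utils::write.table(txt, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write SAN specifications as JSON
#'
#' The JSON layout has fields `sizes` (local state counts), `mhn` (flag)
#' and `transitions`: a list of records with `automaton` (1-based), `from`,
#' `to` (0-based local states) and `effects` (a list of `d` numeric vectors,
#' one per automaton).
#'
#' @param path file path.
#' @param spec a [san_spec()].
#' @return `read_san_spec` returns a validated `san_spec`; `write_san_spec`
#'   returns `path` invisibly.
#' @export
read_san_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sizes <- as.integer(unlist(obj$sizes))
  d <- length(sizes)
  transitions <- rep(list(list()), d)
  for (rec in obj$transitions) {
    i <- as.integer(rec$automaton)
    if (is.na(i) || i < 1L || i > d)
      stop("transition record references automaton ", rec$automaton)
    tr <- list(from = as.integer(rec$from), to = as.integer(rec$to),
               effects = lapply(rec$effects, function(e) as.numeric(unlist(e))))
    transitions[[i]] <- c(transitions[[i]], list(tr))
  }
  san_spec(sizes, transitions, mhn = isTRUE(obj$mhn),
           theta = if (!is.null(obj$theta))
             theta_matrix(do.call(rbind, lapply(obj$theta, unlist))))
}

#' @rdname read_san_spec
#' @export
write_san_spec <- function(spec, path) {
  stopifnot(inherits(spec, "san_spec"))
  recs <- list()
  for (i in seq_len(spec$d)) {
    for (tr in spec$transitions[[i]]) {
      recs <- c(recs, list(list(automaton = i, from = tr$from, to = tr$to,
                                effects = tr$effects)))
    }
  }
  obj <- list(sizes = spec$sizes, mhn = spec$mhn, transitions = recs)
  if (!is.null(spec$theta)) obj$theta <- spec$theta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Serialize hierarchical Tucker tensors
#'
#' Writes an `ht_tensor` to a versioned JSON container holding the mode
#' sizes, the tree's leaf order, and per node its mode label set and frame
#' or transfer array. Round-trips exactly (numbers are written at full
#' precision).
#'
#' @param x an `ht_tensor`.
#' @param path file path.
#' @return `read_ht_json` returns the `ht_tensor`; `write_ht_json` returns
#'   `path` invisibly.
#' @export
write_ht_json <- function(x, path) {
  stopifnot(is_ht_tensor(x))
  nodes <- lapply(seq_len(x$tree$nnodes), function(t) {
    dat <- x$data[[t]]
    list(modes = x$tree$modes[[t]], dim = dim(dat),
         values = as.vector(dat))
  })
  obj <- list(format = "htmarginal-ht-1", d = x$tree$d, dims = x$dims,
              leaf_order = x$tree$leaf_order, nodes = nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ht_json
#' @export
read_ht_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "htmarginal-ht-1"))
    stop("not an htmarginal HT container (format tag: ",
         format(obj$format), ")")
  d <- as.integer(obj$d)
  tree <- balanced_tree(d, as.integer(unlist(obj$leaf_order)))
  data <- vector("list", tree$nnodes)
  for (t in seq_len(tree$nnodes)) {
    node <- obj$nodes[[t]]
    if (!identical(as.integer(unlist(node$modes)), tree$modes[[t]]))
      stop("node ", t, " label set does not match the declared tree")
    dm <- as.integer(unlist(node$dim))
    vals <- as.numeric(unlist(node$values))
    data[[t]] <- if (length(dm) == 2L) matrix(vals, dm[1L], dm[2L])
                 else array(vals, dm)
  }
  new_ht(tree, as.integer(unlist(obj$dims)), data)
}
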