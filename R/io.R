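#' Read a disease-miRNA association list
#'
#' Reads a two-column tab-separated file of known associations, one
#' `disease_id TAB mirna_id` pair per line.  Lines starting with `#` and
#' blank lines are skipped; identifiers are trimmed of surrounding
#' whitespace and matched case-sensitively (disease names routinely contain
#' internal spaces, so only the surrounding whitespace is removed).
#' Duplicate pairs are dropped, keeping first-appearance order.
#'
#' @param path Path to a TSV file.
#' @return A data frame with character columns `disease` and `mirna`, one
#'   row per distinct association.
#' @seealso [build_adjacency()] to turn the table into a binary matrix.
#' @export
read_associations <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(disease = character(), mirna = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed association line %d in '%s': expected 2 tab-separated fields",
                 attr(lines, "line_numbers")[bad[1L]], path))
  }
  disease <- trimws(vapply(fields, `[[`, "", 1L))
  mirna   <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(disease == "" | mirna == "")) {
    i <- which(disease == "" | mirna == "")[1L]
    stop(sprintf("empty identifier on line %d of '%s'",
                 attr(lines, "line_numbers")[i], path))
  }
  tab <- data.frame(disease = disease, mirna = mirna, stringsAsFactors = FALSE)
  tab[!duplicated(paste(disease, mirna, sep = "\r")), , drop = FALSE]
}

# Non-comment, non-blank lines of a UTF-8 text file, with original line
# numbers attached for error reporting.
read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  out <- raw[keep]
  attr(out, "line_numbers") <- which(keep)
  out
}

#' Build the binary disease x miRNA adjacency matrix
#'
#' Rows index diseases, columns index miRNAs; entry (i, j) is 1 exactly when
#' the pair is present in `table`.  Label order follows the explicit
#' `diseases` / `mirnas` vectors when given, otherwise first appearance in
#' the table.
#'
#' @param table Association data frame as returned by [read_associations()]
#'   (columns `disease`, `mirna`).
#' @param diseases,mirnas Optional explicit identifier orderings; must cover
#'   every identifier used in `table`.
#' @return A numeric 0/1 matrix with `dimnames = list(diseases, mirnas)`.
#' @export
build_adjacency <- function(table, diseases = NULL, mirnas = NULL) {
  stopifnot(is.data.frame(table), all(c("disease", "mirna") %in% names(table)))
  key <- paste(table$disease, table$mirna, sep = "\r")
  table <- table[!duplicated(key), , drop = FALSE]
  if (is.null(diseases)) diseases <- unique(table$disease)
  if (is.null(mirnas))   mirnas   <- unique(table$mirna)
  if (anyDuplicated(diseases) || anyDuplicated(mirnas)) {
    stop("explicit identifier lists must not contain duplicates")
  }
  missing_d <- setdiff(table$disease, diseases)
  if (length(missing_d) > 0L) {
    stop(sprintf("disease '%s' appears in the table but not in the supplied disease list",
                 missing_d[1L]))
  }
  missing_m <- setdiff(table$mirna, mirnas)
  if (length(missing_m) > 0L) {
    stop(sprintf("miRNA '%s' appears in the table but not in the supplied miRNA list",
                 missing_m[1L]))
  }
  a <- matrix(0, nrow = length(diseases), ncol = length(mirnas),
              dimnames = list(diseases, mirnas))
  a[cbind(match(table$disease, diseases), match(table$mirna, mirnas))] <- 1
  a
}

#' Read a disease hierarchy
#'
#' Reads a `child_id TAB parent_id` edge list describing a MeSH-like
#' hierarchy and validates that the directed graph is acyclic.  Each
#' disease's DAG (the disease plus its ancestor closure) is later derived
#' from these edges for semantic similarity.
#'
#' @param path Path to a TSV edge file.
#' @return An object of class `disease_hierarchy`: a list with `edges`
#'   (data frame `child`, `parent`) and `nodes` (character vector).
#' @export
read_hierarchy <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(disease_hierarchy(data.frame(child = character(), parent = character(),
                                        stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed hierarchy line %d in '%s': expected child TAB parent",
                 attr(lines, "line_numbers")[bad[1L]], path))
  }
  child  <- trimws(vapply(fields, `[[`, "", 1L))
  parent <- trimws(vapply(fields, `[[`, "", 2L))
  disease_hierarchy(data.frame(child = child, parent = parent,
                               stringsAsFactors = FALSE))
}

#' Construct a disease hierarchy from an edge data frame
#'
#' @param edges Data frame with character columns `child` and `parent`.
#' @return A validated `disease_hierarchy` object.
#' @export
disease_hierarchy <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges <- unique(edges[, c("child", "parent")])
  if (any(edges$child == edges$parent)) {
    i <- which(edges$child == edges$parent)[1L]
    stop(sprintf("self-edge in hierarchy: '%s'", edges$child[i]))
  }
  nodes <- unique(c(edges$child, edges$parent))
  h <- structure(list(edges = edges, nodes = nodes), class = "disease_hierarchy")
  cyc <- find_cycle(h)
  if (!is.null(cyc)) {
    stop(sprintf("hierarchy contains a cycle: %s", paste(cyc, collapse = " -> ")))
  }
  h
}

# Returns one directed cycle (as a node vector) if any exists, else NULL.
# Iterative DFS over the child -> parent edges.
find_cycle <- function(h) {
  parents <- split(h$edges$parent, h$edges$child)
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  for (start in h$nodes) {
    if (!is.null(state[[start]])) next
    stack <- list(list(node = start, next_i = 1L))
    path <- start
    state[[start]] <- 1L
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      kids <- parents[[top$node]]
      if (is.null(kids) || top$next_i > length(kids)) {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
        next
      }
      stack[[length(stack)]]$next_i <- top$next_i + 1L
      nxt <- kids[top$next_i]
      s <- state[[nxt]]
      if (is.null(s)) {
        state[[nxt]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = nxt, next_i = 1L)
        path <- c(path, nxt)
      } else if (s == 1L) {
        i <- match(nxt, path)
        return(c(path[i:length(path)], nxt))
      }
    }
  }
  NULL
}

#' @export
print.disease_hierarchy <- function(x, ...) {
  cat(sprintf("<disease_hierarchy> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read / write a labelled similarity matrix
#'
#' The on-disk format is a TSV: a header line `id TAB id_1 ... id_n`
#' followed by one line per row (`id_i TAB v_i1 ... v_in`).  Values are
#' written with 17 significant digits so that `write_matrix()` followed by
#' `read_matrix()` reproduces the matrix to better than 1e-12.
#' `read_matrix()` checks that the matrix is square, symmetric (to 1e-8)
#' and non-negative, the invariants every similarity role shares.
#'
#' @param path File path.
#' @param check If `FALSE`, skip the symmetry/non-negativity validation
#'   (score matrices are general real matrices).
#' @return `read_matrix()` returns a numeric matrix with identical row and
#'   column names; `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, check = TRUE) {
  lines <- read_data_lines(path)
  if (length(lines) < 2L) stop(sprintf("matrix file '%s' is empty", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ids <- trimws(header[-1L])
  n <- length(ids)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (length(body) != n) {
    stop(sprintf("matrix file '%s' is not square: %d ids, %d rows",
                 path, n, length(body)))
  }
  row_ids <- trimws(vapply(body, `[[`, "", 1L))
  vals <- vapply(body, function(f) {
    if (length(f) != n + 1L) stop(sprintf("row '%s' has %d values, expected %d",
                                          f[1L], length(f) - 1L, n))
    as.numeric(f[-1L])
  }, numeric(n))
  m <- t(matrix(vals, nrow = n))
  dimnames(m) <- list(row_ids, ids)
  if (!identical(row_ids, ids)) {
    stop(sprintf("matrix file '%s': row ids do not match header ids", path))
  }
  if (anyNA(m)) stop(sprintf("matrix file '%s' contains non-numeric entries", path))
  if (check) {
    if (max(abs(m - t(m))) > 1e-8) stop(sprintf("matrix in '%s' is not symmetric", path))
    if (min(m) < 0) stop(sprintf("matrix in '%s' has negative entries", path))
  }
  m
}

#' @rdname read_matrix
#' @param m A numeric matrix with row and column names.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write ranked predictions
#'
#' Writes a TSV of `(disease_id, mirna_id, score, rank, known)` rows,
#' sorted by descending score within each disease.  `known` is 1 for pairs
#' present in the adjacency matrix (already verified associations) and 0
#' for candidate pairs; ranks are assigned within each disease over all its
#' miRNAs.
#'
#' @param scores Score matrix (diseases x miRNAs) as produced by
#'   [kronrls_solve()] or [mda_predict()].
#' @param adjacency Binary adjacency matrix with the same dimnames.
#' @param path Output file path.
#' @param top_k Optional: keep only the `top_k` best-scoring miRNAs per
#'   disease.
#' @return The output path, invisibly.
#' @export
write_predictions <- function(scores, adjacency, path, top_k = NULL) {
  stopifnot(identical(dimnames(scores), dimnames(adjacency)))
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    o <- order(scores[i, ], decreasing = TRUE)
    k <- if (is.null(top_k)) length(o) else min(top_k, length(o))
    o <- o[seq_len(k)]
    data.frame(disease = rownames(scores)[i],
               mirna = colnames(scores)[o],
               score = scores[i, o],
               rank = seq_len(k),
               known = as.integer(adjacency[i, o] != 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("disease\tmirna\tscore\trank\tknown", con)
  writeLines(sprintf("%s\t%s\t%.12g\t%d\t%d",
                     out$disease, out$mirna, out$score, out$rank, out$known), con)
  invisible(path)
}

#' @rdname read_associations
#' @param table Association data frame.
#' @export
write_associations <- function(table, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(table) > 0L) {
    writeLines(paste(table$disease, table$mirna, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname read_hierarchy
#' @param h A `disease_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(h$edges) > 0L) {
    writeLines(paste(h$edges$child, h$edges$parent, sep = "\t"), con)
  }
  invisible(path)
}
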