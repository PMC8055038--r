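#' Pairwise chi-squared screen over candidate items
#'
#' Pearson chi-squared test (no continuity correction) for every unordered
#' pair of items, each pair cross-tabulated on its pairwise-complete rows.
#' Pairs whose 2x2 table has a zero margin are flagged degenerate and
#' excluded from significance counting.
#'
#' @param data data.frame of categorical columns (binary items or any
#'   factors, e.g. province).
#' @param items columns to cross (default: `items` attribute).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per pair: `variable_a`, `variable_b`,
#'   `statistic`, `dof`, `p_value`, `significant`, `degenerate`.
#' @export
pairwise_chi2 <- function(data, items = attr(data, "items"), alpha = 0.05) {
  if (is.null(items)) items <- setdiff(names(data), c("id", "province", "outcome"))
  if (length(items) < 2) stopf("need at least two items")
  pairs <- utils::combn(items, 2)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ok <- !is.na(data[[a]]) & !is.na(data[[b]])
    tab <- table(factor(data[[a]][ok]), factor(data[[b]][ok]))
    degenerate <- nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      data.frame(variable_a = a, variable_b = b, statistic = NA_real_,
                 dof = NA_integer_, p_value = NA_real_, significant = NA,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable_a = a, variable_b = b,
                 statistic = unname(ct$statistic),
                 dof = as.integer(ct$parameter), p_value = unname(ct$p.value),
                 significant = unname(ct$p.value) < alpha,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  out
}

#' Multiple correspondence analysis of a binary item set
#'
#' Correspondence analysis of the N x 2Q indicator (dummy) matrix:
#' relative frequencies, standardized residuals from row/column masses,
#' singular value decomposition. Principal inertias are the squared
#' singular values; for Q binary variables the total inertia is
#' (2Q / Q) - 1 = 1. Category principal coordinates are standard
#' coordinates scaled by the singular values. The optional Benzecri
#' adjustment re-expresses inertias of dimensions with eigenvalue above
#' 1/Q; raw inertias are the default.
#'
#' @param data complete-case item data.frame of 0/1 columns.
#' @param items item columns (default: `items` attribute).
#' @param adjust_inertia apply the Benzecri adjustment to
#'   `explained_inertia` (raw eigenvalues are always returned).
#' @return object of class `mca_solution`: `category_coordinates`
#'   ((2Q) x D matrix, rows named `item:level`), `eigenvalues`,
#'   `total_inertia`, `explained_inertia`, `singular_values`, `column_masses`.
#' @export
mca <- function(data, items = attr(data, "items"), adjust_inertia = FALSE) {
  if (is.null(items)) items <- setdiff(names(data), c("id", "province", "outcome"))
  X <- as.matrix(data[, items, drop = FALSE])
  if (anyNA(X)) stopf("mca requires complete cases")
  Q <- length(items)
  constant <- items[apply(X, 2, function(v) length(unique(v)) < 2)]
  if (length(constant))
    stopf("constant column (empty category): %s",
          paste(constant, collapse = ", "))
  Z <- matrix(0L, nrow(X), 2L * Q)
  colnames(Z) <- as.vector(rbind(paste0(items, ":0"), paste0(items, ":1")))
  for (q in seq_len(Q)) {
    Z[, 2L * q - 1L] <- 1L - X[, q]
    Z[, 2L * q] <- X[, q]
  }
  P <- Z / sum(Z)
  r <- rowSums(P); cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  sv <- svd(S)
  D <- min(nrow(X) - 1L, 2L * Q - Q)
  d <- sv$d[seq_len(D)]
  eig <- d^2
  coord <- sweep(sv$v[, seq_len(D), drop = FALSE], 1, sqrt(cm), "/") %*% diag(d, D)
  rownames(coord) <- colnames(Z)
  colnames(coord) <- paste0("dim", seq_len(D))
  expl <- if (adjust_inertia) {
    lam <- eig[eig > 1 / Q]
    adj <- (Q / (Q - 1))^2 * (lam - 1 / Q)^2
    c(adj / sum(adj), rep(0, D - length(adj)))
  } else eig / sum(eig)
  structure(list(category_coordinates = coord, eigenvalues = eig,
                 total_inertia = sum(eig), explained_inertia = expl,
                 singular_values = d, column_masses = cm, n_vars = Q),
            class = "mca_solution")
}

#' @export
print.mca_solution <- function(x, ...) {
  cat(sprintf("MCA of %d binary variables: total inertia %.4f\n",
              x$n_vars, x$total_inertia))
  cat(sprintf("  first two dimensions explain %.1f%% + %.1f%% of inertia\n",
              100 * x$explained_inertia[1], 100 * x$explained_inertia[2]))
  invisible(x)
}

#' Variable-screening report
#'
#' Combines the chi-squared screen and the MCA into a per-variable summary:
#' number of significant pairings, coordinates of the deprived category on
#' the first two MCA dimensions, and the nearest-neighbour variable in MCA
#' space. The final item list is configuration-driven (the screening
#' informs an expert choice, it does not automate one); the default is the
#' nine retained indicators.
#'
#' @param chi2 result of [pairwise_chi2()] (or NULL for MCA-only).
#' @param mca_sol result of [mca()].
#' @param final_items character vector naming the retained items.
#' @return object of class `selection_report` with elements `summary`
#'   (data.frame), `final_items`, `n_candidates`.
#' @export
selection_report <- function(chi2, mca_sol, final_items = core9_items()) {
  stopifnot(inherits(mca_sol, "mca_solution"))
  cats <- rownames(mca_sol$category_coordinates)
  dep <- grepl(":1$", cats)
  vars <- sub(":1$", "", cats[dep])
  co <- mca_sol$category_coordinates[dep, 1:2, drop = FALSE]
  dmat <- as.matrix(stats::dist(co))
  diag(dmat) <- Inf
  nn <- vars[apply(dmat, 1, which.min)]
  nsig <- vapply(vars, function(v) {
    if (is.null(chi2) || !nrow(chi2)) return(NA_integer_)
    rows <- (chi2$variable_a == v | chi2$variable_b == v) & !chi2$degenerate
    sum(chi2$significant[rows], na.rm = TRUE)
  }, 0L)
  summary <- data.frame(variable = vars, n_significant = nsig,
                        dim1 = co[, 1], dim2 = co[, 2],
                        nearest_neighbour = nn,
                        selected = vars %in% final_items,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, final_items = final_items,
                 n_candidates = length(vars)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Variable screening: %d candidates, %d selected\n",
              x$n_candidates, length(x$final_items)))
  print(x$summary, digits = 3)
  invisible(x)
}
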