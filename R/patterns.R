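#' Default catalog of 12 three-condition pattern vectors
#'
#' Templates of CpG methylation over (proB, WT mature, KO mature) with
#' components drawn from low = 0.2, intermediate = 0.5, high = 0.8. The set
#' covers the canonical trajectories: developmental hypomethylation kept low
#' in the knockout (P1), DNMT3A-dependent maintenance lost only in the
#' knockout (P2, P3, P6), developmental gain (P4, P9), knockout-insensitive
#' dynamics (P5), developmental loss completed by knockout (P7, P8), and
#' paradoxical knockout gain (P10, P11, P12). The exact template set is a
#' reconstruction and is deliberately data, not code: pass any catalog with
#' the same columns to the assignment functions.
#'
#' @return Data frame `id, proB, WT, KO, label`; all vectors non-constant
#'   (a constant template has no defined correlation with anything).
#' @export
default_pattern_catalog <- function() {
  data.frame(
    id = paste0("P", 1:12),
    proB = c(0.8, 0.8, 0.5, 0.2, 0.8, 0.5, 0.8, 0.5, 0.2, 0.8, 0.5, 0.2),
    WT   = c(0.2, 0.8, 0.5, 0.8, 0.5, 0.8, 0.5, 0.2, 0.5, 0.2, 0.2, 0.2),
    KO   = c(0.2, 0.2, 0.2, 0.2, 0.5, 0.2, 0.2, 0.2, 0.2, 0.5, 0.8, 0.8),
    label = c("developmental loss, KO low",
              "maintained high, KO loss",
              "maintained intermediate, KO loss",
              "developmental gain, KO loss",
              "developmental loss, KO-insensitive",
              "intermediate-to-high gain, KO loss",
              "developmental loss, complete KO loss",
              "partial developmental loss, KO low",
              "partial developmental gain, KO loss",
              "developmental loss, partial KO regain",
              "developmental loss, KO gain",
              "KO-specific gain"),
    stringsAsFactors = FALSE)
}

#' Read / write a pattern catalog
#'
#' Tab-separated with a header: `id` plus the three level columns
#' `proB, WT, KO`.
#'
#' @param path file path.
#' @return Data frame catalog.
#' @export
read_pattern_catalog <- function(path) {
  ct <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("id", "proB", "WT", "KO") %in% names(ct)))
    stop("pattern catalog needs columns id, proB, WT, KO")
  ct
}

#' @rdname read_pattern_catalog
#' @param catalog data frame catalog.
#' @export
write_pattern_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign condition-methylation vectors to pattern templates by maximum PCC
#'
#' Each observed 3-vector is assigned to the catalog template with the
#' maximum Pearson correlation coefficient; no vector is assigned to more
#' than one pattern. Because the PCC of 3-point vectors is invariant to
#' affine rescaling, several {0.2, 0.5, 0.8} templates can tie exactly;
#' ties (within `1e-9`) are broken by minimal Euclidean distance to the
#' observed vector, then by catalog order, preserving the low/intermediate/
#' high magnitude semantics. Constant observed vectors have undefined
#' correlation and are left unassigned.
#'
#' @param v numeric 3-vector, or a matrix / data frame with one row per
#'   region and columns `(proB, WT, KO)`.
#' @param catalog pattern catalog (default [default_pattern_catalog()]).
#' @return Data frame `pattern, pcc, runner_up, runner_up_pcc`, one row per
#'   input vector; `pattern` is `NA` for unassigned (constant) vectors.
#' @export
assign_pattern <- function(v, catalog = default_pattern_catalog()) {
  tmpl <- as.matrix(catalog[, c("proB", "WT", "KO")])
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  if (ncol(v) != ncol(tmpl))
    stop("observed vectors and catalog templates differ in length")
  if (any(stats::na.omit(c(v)) < 0 | stats::na.omit(c(v)) > 1))
    stop("methylation vectors must lie in [0,1]")
  tied_tol <- 1e-9
  rows <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    if (anyNA(x) || stats::sd(x) == 0)
      return(data.frame(pattern = NA_character_, pcc = NA_real_,
                        runner_up = NA_character_,
                        runner_up_pcc = NA_real_))
    pcc <- apply(tmpl, 1, function(tm) cor(x, tm))
    best_pcc <- max(pcc)
    tied <- which(pcc >= best_pcc - tied_tol)
    if (length(tied) > 1) {
      d2 <- rowSums((tmpl[tied, , drop = FALSE] -
                       matrix(x, length(tied), 3, byrow = TRUE))^2)
      tied <- tied[order(d2, tied)]  # distance, then catalog order
    }
    win <- tied[1]
    rest <- setdiff(order(pcc, decreasing = TRUE), win)
    data.frame(pattern = catalog$id[win], pcc = pcc[win],
               runner_up = catalog$id[rest[1]],
               runner_up_pcc = pcc[rest[1]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign patterns to a DDMR table
#'
#' Convenience wrapper over [assign_pattern()] taking the output of
#' [construct_ddmrs()].
#'
#' @param ddmrs data frame with columns `mean_proB, mean_WT, mean_KO`.
#' @param catalog pattern catalog.
#' @return `ddmrs` with `pattern`, `pcc`, `runner_up`, `runner_up_pcc`
#'   columns appended.
#' @export
assign_patterns <- function(ddmrs, catalog = default_pattern_catalog()) {
  v <- as.matrix(ddmrs[, c("mean_proB", "mean_WT", "mean_KO")])
  cbind(ddmrs, assign_pattern(v, catalog))
}

#' Summarise pattern assignments
#'
#' @param assignments output of [assign_pattern()] / [assign_patterns()].
#' @return Data frame `pattern, n, fraction` over assigned regions
#'   (fractions sum to 1), with the unassigned count in attribute
#'   `n_unassigned`.
#' @export
summarize_patterns <- function(assignments) {
  p <- assignments$pattern
  assigned <- p[!is.na(p)]
  if (!length(assigned)) {
    out <- data.frame(pattern = character(), n = integer(),
                      fraction = numeric())
    attr(out, "n_unassigned") <- sum(is.na(p))
    return(out)
  }
  tab <- table(assigned)
  out <- data.frame(pattern = names(tab), n = as.integer(tab),
                    fraction = as.integer(tab) / length(assigned))
  out <- out[order(-out$n, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- sum(is.na(p))
  out
}
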