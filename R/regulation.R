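#' Read a long-format qRT-PCR Ct table
#'
#' Expects tab-separated columns `gene`, `condition`, `replicate`, `Ct`.
#' The reference gene (default `rpoD`, a constitutively transcribed sigma
#' factor) must be measured in every condition.
#'
#' @param path TSV path.
#' @param reference reference (normalizer) gene id.
#' @param control control condition id.
#' @return A data.frame of class `"cpx_ct"` with attributes `reference`
#'   and `control`.
#' @export
read_ct_table <- function(path, reference = "rpoD", control = "control") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ct_table(df, reference = reference, control = control)
}

#' @rdname read_ct_table
#' @param df a data.frame with columns `gene`, `condition`, `replicate`,
#'   `Ct`.
#' @export
ct_table <- function(df, reference = "rpoD", control = "control") {
  need <- c("gene", "condition", "replicate", "Ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(df$Ct)) || any(df$Ct <= 0)) {
    stop("Ct values must be finite positive numbers")
  }
  conds <- unique(df$condition)
  if (!(control %in% conds)) stop("control condition absent from table")
  for (cc in conds) {
    if (!(reference %in% df$gene[df$condition == cc])) {
      stop("reference gene '", reference, "' missing in condition '", cc, "'")
    }
  }
  structure(df, reference = reference, control = control,
            class = c("cpx_ct", "data.frame"))
}

mean_ct <- function(ct, gene, condition) {
  v <- ct$Ct[ct$gene == gene & ct$condition == condition]
  if (!length(v)) {
    stop("no Ct measurements for gene '", gene, "' in condition '",
         condition, "'")
  }
  mean(v)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' `fold = 2^(-ddCt)` with
#' `ddCt = (Ct_gene - Ct_ref)_condition - (Ct_gene - Ct_ref)_control`,
#' where each Ct is the arithmetic mean over replicates. Fold changes are
#' invariant to adding a constant to every Ct (plate offsets cancel).
#'
#' @param ct a [ct_table()].
#' @param gene target gene id.
#' @param condition condition id to contrast against the table's control.
#' @return The fold change (positive real).
#' @export
ddct_fold <- function(ct, gene, condition) {
  ref <- attr(ct, "reference")
  ctl <- attr(ct, "control")
  d_cond <- mean_ct(ct, gene, condition) - mean_ct(ct, ref, condition)
  d_ctl <- mean_ct(ct, gene, ctl) - mean_ct(ct, ref, ctl)
  2^(-(d_cond - d_ctl))
}

#' Call one fold-change value against the 2-fold rule
#'
#' `positive` when `fold >= threshold`, `negative` when
#' `fold <= 1/threshold`, otherwise (including missing values)
#' `insignificant`. Bounds are inclusive: a fold of exactly 2 is a
#' positive call, 0.5 a negative call; only strictly-between-bounds values
#' are insignificant.
#'
#' @param fold a fold change (positive number) or `NA` for a missing cell.
#' @param threshold fold-change cutoff, > 1 (default 2).
#' @return One of `"positive"`, `"negative"`, `"insignificant"`.
#' @export
fold_call <- function(fold, threshold = 2) {
  if (threshold <= 1) stop("threshold must exceed 1")
  vapply(fold, function(f) {
    if (is.na(f)) return("insignificant")
    if (f <= 0) stop("fold changes must be positive")
    if (f >= threshold) "positive"
    else if (f <= 1 / threshold) "negative"
    else "insignificant"
  }, character(1L))
}

#' Read a wide fold-change table
#'
#' Mirrors the layout of a published qRT-PCR summary: one row per gene, one
#' column per strain comparison, with an em dash (or `-`, `NA`, empty) for
#' cells below the reporting threshold. Columns are assigned to activation
#' groups by name via `groups`.
#'
#' @param path TSV path; first column must be `gene`.
#' @param groups named list mapping group ids to column-name vectors, e.g.
#'   `list(g1 = c("cpxA24", "dcpxA"), g2 = c("pnlpE", "dcpxR_pnlpE"))`.
#' @return A data.frame of class `"cpx_folds"` (gene column plus numeric
#'   fold columns, `NA` for missing) with attribute `groups`.
#' @export
read_fold_table <- function(path, groups) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "-", "—"))
  fold_table(df, groups)
}

#' @rdname read_fold_table
#' @param df data.frame with a `gene` column and numeric fold columns.
#' @export
fold_table <- function(df, groups) {
  if (!"gene" %in% names(df)) stop("fold table needs a 'gene' column")
  cols <- unlist(groups, use.names = FALSE)
  if (!all(cols %in% names(df))) {
    stop("group columns absent from table: ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  }
  for (cc in cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(!is.na(df[[cc]]) & df[[cc]] <= 0)) {
      stop("fold changes must be positive (column ", cc, ")")
    }
  }
  structure(df, groups = groups, class = c("cpx_folds", "data.frame"))
}

#' Per-gene regulation verdicts
#'
#' A gene's verdict for an activation group is decided from the group's
#' columns: the direction of the first column (in the order given by the
#' table's `groups`) whose fold meets the rule, `insignificant` when none
#' does. A gene counts as regulated in
#' a group when either of the group's columns meets the 2-fold rule in
#' either direction. The overall `regulated` flag is true when at least
#' one group verdict is non-insignificant.
#'
#' @param folds a [fold_table()].
#' @param threshold fold cutoff (default 2).
#' @return A data.frame: `gene`, one `<group>_verdict` column per group,
#'   and logical `regulated`.
#' @export
regulation_calls <- function(folds, threshold = 2) {
  groups <- attr(folds, "groups")
  out <- data.frame(gene = folds$gene)
  any_reg <- rep(FALSE, nrow(folds))
  for (gname in names(groups)) {
    # direction comes from the first significant column in group order
    verdict <- rep("insignificant", nrow(folds))
    for (cc in rev(groups[[gname]])) {
      calls <- fold_call(folds[[cc]], threshold)
      verdict[calls != "insignificant"] <- calls[calls != "insignificant"]
    }
    out[[paste0(gname, "_verdict")]] <- verdict
    any_reg <- any_reg | verdict != "insignificant"
  }
  out$regulated <- any_reg
  out
}

#' Count regulated genes in one activation group
#'
#' @param folds a [fold_table()].
#' @param group a group id from the table's `groups` attribute.
#' @param threshold fold cutoff (default 2).
#' @return Number of genes with at least one non-missing group column
#'   calling positive or negative.
#' @export
count_regulated <- function(folds, group, threshold = 2) {
  groups <- attr(folds, "groups")
  if (!group %in% names(groups)) stop("unknown group '", group, "'")
  calls <- regulation_calls(folds, threshold)
  sum(calls[[paste0(group, "_verdict")]] != "insignificant")
}

#' Count genes regulated in at least one activation group
#'
#' @inheritParams count_regulated
#' @return Number of distinct regulated genes across all groups.
#' @export
count_union <- function(folds, threshold = 2) {
  sum(regulation_calls(folds, threshold)$regulated)
}
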