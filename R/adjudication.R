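# Best-pose adjudication and ligand ranking.  A selected orientation type
# is "correct" when its in-place heavy-atom RMSD to the crystallised ligand
# geometry is <= 2.0 A; per-target summaries count correct calls for the
# docking fitness score and for the KEM-CP averaged IE, and ligand rankings
# by either key are compared against experimental IC50 values.

#' Load a packaged ligand-record table
#'
#' Long-format records of the three benchmark targets (human aldose
#' reductase, cyclin-dependent kinase 2, estrogen receptor beta): one row
#' per ligand and orientation type with the averaged interaction energy,
#' docking fitness score and rank, RMSD to the crystal ligand geometry,
#' and experimental IC50.  An absent type (no poses) has no row; a type
#' whose IE calculation failed has `NA` in `avg_ie`.
#'
#' @param target `"hAR"`, `"CDK2"` or `"ERbeta"`
#' @return data.frame with columns `ligand_id`, `ic50_nM`, `ic50_err`,
#'   `pose_type`, `avg_ie`, `fitness`, `gold_rank`, `rmsd`
#' @export
lead_table <- function(target = c("hAR", "CDK2", "ERbeta")) {
  target <- match.arg(target)
  f <- c(hAR = "table2_3_hAR.csv", CDK2 = "table4_5_CDK2.csv",
         ERbeta = "table6_7_ERbeta.csv")[[target]]
  path <- system.file("extdata", f, package = "kemlead", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Adjudicate best-pose selections for each ligand
#'
#' For every ligand the best orientation type is selected twice — by
#' maximum fitness and by most negative averaged IE (failed/missing IEs
#' skipped) — and each selection is called correct iff its RMSD to the
#' crystal geometry is within `rmsd_cutoff`.
#'
#' @param records long-format data.frame as returned by [lead_table()]
#' @param rmsd_cutoff correctness cutoff in Angstrom (default 2.0)
#' @return data.frame, one row per ligand: `ligand_id`,
#'   `fitness_type`, `fitness_rmsd`, `fitness_correct`,
#'   `ie_type`, `ie_rmsd`, `ie_correct`
#' @export
adjudicate <- function(records, rmsd_cutoff = 2.0) {
  per_ligand <- split(records, records$ligand_id)
  rows <- lapply(per_ligand, function(r) {
    ft <- r$pose_type[[which.max(r$fitness)]]
    ie_ok <- !is.na(r$avg_ie)
    if (!any(ie_ok)) stop("ligand ", r$ligand_id[[1]], ": all IEs missing")
    it <- r$pose_type[ie_ok][[which.min(r$avg_ie[ie_ok])]]
    f_rmsd <- r$rmsd[[match(ft, r$pose_type)]]
    i_rmsd <- r$rmsd[[match(it, r$pose_type)]]
    if (is.na(f_rmsd) || is.na(i_rmsd))
      stop("ligand ", r$ligand_id[[1]], ": missing RMSD for selected type")
    data.frame(ligand_id = r$ligand_id[[1]],
               fitness_type = ft, fitness_rmsd = f_rmsd,
               fitness_correct = f_rmsd <= rmsd_cutoff,
               ie_type = it, ie_rmsd = i_rmsd,
               ie_correct = i_rmsd <= rmsd_cutoff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$ligand_id, unique(records$ligand_id))), ,
      drop = FALSE]
}

#' Summarise correct-pose predictions for one target
#'
#' Counts and integer-rounded percentages of ligands whose best pose —
#' selected by docking fitness and by averaged IE — is correct.
#'
#' @param records long-format records ([lead_table()] layout), or an
#'   [adjudicate()] result
#' @param rmsd_cutoff passed to [adjudicate()] when `records` is raw
#' @return one-row data.frame: `n_ligands`, `fitness_correct`,
#'   `ie_correct`, `fitness_pct`, `ie_pct`
#' @export
summarize_target <- function(records, rmsd_cutoff = 2.0) {
  adj <- if (!is.null(records$fitness_correct)) records
         else adjudicate(records, rmsd_cutoff)
  n <- nrow(adj)
  fc <- sum(adj$fitness_correct)
  ic <- sum(adj$ie_correct)
  data.frame(n_ligands = n, fitness_correct = fc, ie_correct = ic,
             fitness_pct = as.integer(round(100 * fc / n)),
             ie_pct = as.integer(round(100 * ic / n)))
}

#' Rank ligands by IC50, averaged IE or fitness
#'
#' IC50 ranks ascending (smaller = more potent = rank 1); averaged IE
#' ascending (more negative = better); fitness descending.  Ties share the
#' mean rank.  Scope `"best-pose"` takes each ligand's best value across
#' its types; `"fixed-type"` uses one named orientation type for every
#' ligand.
#'
#' @param records long-format records ([lead_table()] layout)
#' @param key `"ic50"`, `"avg_ie"` or `"fitness"`
#' @param scope `"best-pose"` or `"fixed-type"`
#' @param type orientation type for `scope = "fixed-type"`
#' @return named numeric vector of ranks (names = ligand ids)
#' @export
rank_ligands <- function(records, key = c("ic50", "avg_ie", "fitness"),
                         scope = c("best-pose", "fixed-type"), type = 1L) {
  key <- match.arg(key)
  scope <- match.arg(scope)
  per_ligand <- split(records, records$ligand_id)
  val <- vapply(per_ligand, function(r) {
    if (scope == "fixed-type" && key != "ic50") {
      r <- r[r$pose_type == type, , drop = FALSE]
      if (nrow(r) == 0) return(NA_real_)
    }
    switch(key,
           ic50 = r$ic50_nM[[1]],
           avg_ie = if (all(is.na(r$avg_ie))) NA_real_
                    else min(r$avg_ie, na.rm = TRUE),
           fitness = max(r$fitness))
  }, numeric(1))
  if (anyNA(val))
    stop("missing ", key, " value for ligand(s): ",
         paste(names(val)[is.na(val)], collapse = ", "))
  if (key == "fitness") val <- -val
  ranks <- rank(val, ties.method = "average")
  ordered <- unique(records$ligand_id)
  stats::setNames(ranks[as.character(ordered)], ordered)
}

#' Agreement between two ligand rankings
#'
#' Rank correlation expressed as a percentage: Spearman by default,
#' Kendall's tau available.  The method used is recorded as an attribute.
#'
#' @param rank_a,rank_b rank vectors over the same ligand set (named
#'   vectors are aligned by name)
#' @param method `"spearman"` or `"kendall"`
#' @return correlation in percent, with attribute `method`
#' @export
rank_agreement <- function(rank_a, rank_b,
                           method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (!is.null(names(rank_a)) && !is.null(names(rank_b))) {
    if (!setequal(names(rank_a), names(rank_b)))
      stop("rankings cover different ligand sets")
    rank_b <- rank_b[names(rank_a)]
  }
  if (length(rank_a) != length(rank_b))
    stop("rankings have different lengths")
  if (length(rank_a) < 3) stop("need at least 3 ligands")
  structure(100 * stats::cor(rank_a, rank_b, method = method),
            method = method)
}
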