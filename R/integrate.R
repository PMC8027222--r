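#' Timepoints shared between two designs
#'
#' Intersection of the timepoints at which both conditions are present in
#' both datasets, ascending in minutes. For the mating-type layouts of the
#' workflow (MT+ at 15/60/180/360/540 min, MT- at 15/60/180 and 600 min)
#' this is 15, 60 and 180 min; the MT- 10 h experiment takes part in the
#' per-dataset analysis but never in integration.
#'
#' @param samples_plus,samples_minus `sample_table`s of the two datasets.
#' @return Numeric vector of shared timepoints in minutes.
#' @export
shared_timepoints <- function(samples_plus, samples_minus) {
  both_cond <- function(s) {
    tab <- table(s$time_min, s$condition)
    as.numeric(rownames(tab))[rowSums(tab > 0) == 2L]
  }
  shared <- intersect(both_cond(samples_plus), both_cond(samples_minus))
  if (length(shared) == 0L) {
    stop("the two datasets share no timepoint with both conditions")
  }
  sort(shared)
}

# Per-gene dataset-level summaries over the shared timepoints.
dataset_calls <- function(dec, filt, shared, equivalence_mode) {
  cols <- as.character(shared)
  missing_tp <- setdiff(cols, colnames(dec$de_confirmed))
  if (length(missing_tp) > 0L) {
    stop("decision table lacks shared timepoint(s): ",
         paste(missing_tp, collapse = ", "))
  }
  de <- dec$de_confirmed[, cols, drop = FALSE]
  eq <- dec$equiv_called[, cols, drop = FALSE]
  tested <- dec$genes$gene_id
  de_any <- rowSums(de) > 0
  # earliest confirmed timepoint, NA when none
  disc <- apply(de, 1, function(r) if (any(r)) shared[which(r)[1L]] else NA_real_)
  equiv_all <- rowSums(eq) == ncol(eq)
  # equivalence only needed at the other side's discovery timepoint is
  # resolved later, so keep the full matrix too
  list(tested = tested, de_any = de_any, discovery = disc,
       equiv_all = equiv_all, equiv = eq, de = de,
       filtered = filt$filtered)
}

#' Cross-dataset gene classification
#'
#' Combines the two datasets' stage-wise decisions over the shared
#' timepoints into the SRB / SRP / SRM partition:
#' \itemize{
#'   \item SRB: threshold-DE confirmed at >= 1 shared timepoint in both
#'     datasets (direction concordance is not required);
#'   \item SRP: confirmed in MT+ and non-responsive in MT-, where
#'     non-responsive means filtered in MT- or equivalent there;
#'   \item SRM: the mirror image;
#'   \item nonresponsive: equivalent-or-filtered in both;
#'   \item unclassified: anything else (e.g. DE in one dataset with
#'     neither equivalence nor filtering in the other) - absence of a DE
#'     call is never taken as evidence of non-response.
#' }
#' The evaluated universe is the union of the two datasets' gene ids; a
#' gene absent from one dataset counts as filtered there. With
#' `equivalence_mode = "all_shared_timepoints"` (default) equivalence must
#' hold at every shared timepoint; `"de_timepoint_only"` only requires it
#' at the other dataset's discovery timepoint. `specificity =
#' "nonsignificance"` replaces the equivalence requirement by mere lack of
#' a confirmed DE call - the naive rule the equivalence test is designed
#' to improve upon, kept for comparison.
#'
#' @param dec_plus,dec_minus `decision_table`s of the two datasets.
#' @param filt_plus,filt_minus `filter_result`s of the two datasets.
#' @param shared Shared timepoints from [shared_timepoints()].
#' @param equivalence_mode `"all_shared_timepoints"` or
#'   `"de_timepoint_only"`.
#' @param specificity `"equivalence"` (default) or `"nonsignificance"`.
#' @return A `gene_classification` data.frame: `gene_id`, `class`,
#'   `discovery_timepoint` (minutes, NA for non-discoveries),
#'   `other_side_status`, with an `evidence` attribute (long data.frame of
#'   dataset/timepoint/call triples for discovered genes).
#' @export
classify_genes <- function(dec_plus, dec_minus, filt_plus, filt_minus,
                           shared,
                           equivalence_mode = c("all_shared_timepoints",
                                                "de_timepoint_only"),
                           specificity = c("equivalence", "nonsignificance")) {
  equivalence_mode <- match.arg(equivalence_mode)
  specificity <- match.arg(specificity)
  cp <- dataset_calls(dec_plus, filt_plus, shared, equivalence_mode)
  cm <- dataset_calls(dec_minus, filt_minus, shared, equivalence_mode)
  universe <- union(union(cp$tested, cp$filtered),
                    union(cm$tested, cm$filtered))
  if (length(universe) == 0L) stop("empty gene universe")

  side <- function(calls, ids) {
    idx <- match(ids, calls$tested)
    tested <- !is.na(idx)
    de_any <- tested & calls$de_any[idx]
    equiv_all <- tested & calls$equiv_all[idx]
    filtered <- ids %in% calls$filtered | (!tested & !de_any)
    disc <- ifelse(tested, calls$discovery[idx], NA_real_)
    list(tested = tested, de_any = de_any, equiv_all = equiv_all,
         filtered = filtered, disc = disc, idx = idx)
  }
  sp <- side(cp, universe)
  sm <- side(cm, universe)

  # equivalence at a specific timepoint (for de_timepoint_only mode)
  equiv_at <- function(calls, idx, tp) {
    ok <- !is.na(idx) & !is.na(tp) & tp %in% shared
    out <- rep(FALSE, length(idx))
    j <- match(as.character(tp[ok]), colnames(calls$equiv))
    out[ok] <- calls$equiv[cbind(idx[ok], j)]
    out
  }

  nonresp_side <- function(s, calls, other_disc) {
    if (specificity == "nonsignificance") return(s$filtered | !s$de_any)
    if (equivalence_mode == "all_shared_timepoints") {
      s$filtered | s$equiv_all
    } else {
      s$filtered | equiv_at(calls, s$idx, other_disc)
    }
  }
  nonresp_minus <- nonresp_side(sm, cm, sp$disc)
  nonresp_plus <- nonresp_side(sp, cp, sm$disc)

  class <- rep("unclassified", length(universe))
  class[sp$de_any & sm$de_any] <- "SRB"
  class[sp$de_any & !sm$de_any & nonresp_minus] <- "SRP"
  class[sm$de_any & !sp$de_any & nonresp_plus] <- "SRM"
  class[!sp$de_any & !sm$de_any & nonresp_plus & nonresp_minus] <- "nonresponsive"

  other_status <- rep("inconclusive", length(universe))
  other_status[class == "SRP" & sm$filtered] <- "filtered"
  other_status[class == "SRP" & !sm$filtered] <- "equivalent"
  other_status[class == "SRM" & sp$filtered] <- "filtered"
  other_status[class == "SRM" & !sp$filtered] <- "equivalent"
  other_status[class == "SRB"] <- "responsive"

  disc_tp <- ifelse(class %in% c("SRB", "SRP"), sp$disc,
                    ifelse(class == "SRM", sm$disc, NA_real_))
  # for SRBs discovered later in MT+ than MT-, keep the earliest overall
  srb <- class == "SRB"
  disc_tp[srb] <- pmin(sp$disc[srb], sm$disc[srb], na.rm = TRUE)

  out <- data.frame(gene_id = universe, class = class,
                    discovery_timepoint = disc_tp,
                    other_side_status = other_status,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_classification", "data.frame")

  disc_genes <- universe[class %in% c("SRB", "SRP", "SRM")]
  if (length(disc_genes) == 0L) {
    attr(out, "evidence") <- data.frame(gene_id = character(0),
                                        dataset = character(0),
                                        time_min = numeric(0),
                                        call = character(0),
                                        stringsAsFactors = FALSE)
    attr(out, "shared_timepoints") <- shared
    return(out)
  }
  ev <- lapply(c("plus", "minus"), function(ds) {
    calls <- if (ds == "plus") cp else cm
    idx <- match(disc_genes, calls$tested)
    do.call(rbind, lapply(seq_along(shared), function(j) {
      tp <- shared[j]
      data.frame(gene_id = disc_genes, dataset = ds, time_min = tp,
                 call = ifelse(is.na(idx), "filtered",
                        ifelse(calls$de[cbind(idx, j)], "de_confirmed",
                        ifelse(calls$equiv[cbind(idx, j)], "equivalent",
                               "inconclusive"))),
                 stringsAsFactors = FALSE)
    }))
  })
  attr(out, "evidence") <- do.call(rbind, ev)
  attr(out, "shared_timepoints") <- shared
  out
}

#' Tabulate a gene classification
#'
#' @param cls A `gene_classification`.
#' @param lfc_plus,lfc_minus Optional named log2-LFC vectors at the
#'   discovery timepoint, used to report direction of change.
#' @return List with `class_counts` (named integer vector over all five
#'   classes), `by_timepoint` (class x discovery-timepoint table) and,
#'   when LFCs are given, `direction` counts of up/down discoveries.
#' @export
classification_report <- function(cls, lfc_plus = NULL, lfc_minus = NULL) {
  lev <- c("SRB", "SRP", "SRM", "nonresponsive", "unclassified")
  counts <- table(factor(cls$class, levels = lev))
  disc <- cls[cls$class %in% c("SRB", "SRP", "SRM"), , drop = FALSE]
  by_tp <- table(factor(disc$class, levels = c("SRB", "SRP", "SRM")),
                 disc$discovery_timepoint)
  out <- list(class_counts = counts, by_timepoint = by_tp)
  if (!is.null(lfc_plus) || !is.null(lfc_minus)) {
    lfc <- ifelse(disc$class == "SRM",
                  lfc_minus[disc$gene_id], lfc_plus[disc$gene_id])
    out$direction <- table(factor(disc$class, levels = c("SRB", "SRP", "SRM")),
                           ifelse(lfc >= 0, "up", "down"))
  }
  out
}
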