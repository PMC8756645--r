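#' Reaction-level expression from transcript TPM
#'
#' Evaluates an AND/OR association tree against a TPM profile: `OR` nodes
#' sum the expression of their children (isoenzymes add capacity), `AND`
#' nodes take the minimum (complex subunits limit capacity), leaves read
#' the transcript's TPM. A transcript absent from the profile contributes
#' 0 TPM with a warning.
#'
#' @param tree association tree from [parse_association()], or `NULL`.
#' @param tpm named numeric vector of TPM values (one timepoint).
#' @return reaction-level TPM; `NA_real_` for a reaction with no
#'   association (not zero: absence of evidence is not silence).
#' @export
reaction_expression <- function(tree, tpm) {
  if (is.null(tree)) return(NA_real_)
  missing <- setdiff(association_transcripts(tree), names(tpm))
  if (length(missing))
    warning("transcript(s) missing from profile, treated as 0 TPM: ",
            paste(missing, collapse = ", "))
  eval_tree <- function(node) {
    if (node$op == "leaf")
      return(if (node$id %in% names(tpm)) unname(tpm[[node$id]]) else 0)
    vals <- vapply(node$children, eval_tree, numeric(1))
    if (node$op == "or") sum(vals) else min(vals)
  }
  eval_tree(tree)
}

#' Switch off reactions with expression below a TPM cut-off
#'
#' Reactions whose reaction-level TPM is strictly below `cutoff` get both
#' flux bounds set to zero. Reactions without an association are left
#' untouched. Idempotent.
#'
#' @param model a `metabolic_model`.
#' @param tpm named TPM vector for one timepoint.
#' @param cutoff TPM threshold (default 1; the rule is strict `<`).
#' @return the modified model.
#' @export
apply_expression_switch <- function(model, tpm, cutoff = 1) {
  for (i in seq_len(nrow(model$reactions))) {
    tree <- model$associations[[i]]
    if (is.null(tree)) next
    val <- suppressWarnings(reaction_expression(tree, tpm))
    if (!is.na(val) && val < cutoff) {
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  }
  model
}

#' Reaction-level differential expression between two timepoints
#'
#' Reaction TPM is computed at both timepoints via [reaction_expression()];
#' the reaction-level log2 fold change uses a pseudocount on both sides.
#' The call is significant when `|log2FC|` exceeds `log2fc_threshold` and
#' at least one associated transcript has `q < q_threshold` in the
#' differential-expression table for this comparison (transcript q-values
#' are combined by minimum).
#'
#' @param tree association tree.
#' @param de differential-expression data.frame with columns
#'   `transcript_id`, `comparison`, `log2FC`, `q_value`.
#' @param tpm_early,tpm_late named TPM vectors for the two timepoints.
#' @param comparison comparison token, e.g. `"T1-T2"`.
#' @param pseudocount TPM added to both sides of the ratio (default 0.5).
#' @param log2fc_threshold,q_threshold significance thresholds
#'   (defaults 0.7 and 0.01).
#' @return list with `log2fc`, `fold_change` (`2^|log2fc|`), `significant`,
#'   and `reason` when not significant.
#' @export
reaction_differential <- function(tree, de, tpm_early, tpm_late,
                                  comparison = NULL,
                                  pseudocount = 0.5,
                                  log2fc_threshold = 0.7,
                                  q_threshold = 0.01) {
  if (is.null(tree))
    return(list(log2fc = NA_real_, fold_change = NA_real_,
                significant = FALSE, reason = "no association"))
  early <- suppressWarnings(reaction_expression(tree, tpm_early))
  late <- suppressWarnings(reaction_expression(tree, tpm_late))
  if (early == 0 && late == 0)
    return(list(log2fc = NA_real_, fold_change = NA_real_,
                significant = FALSE, reason = "no expression at either timepoint"))
  l2fc <- log2((late + pseudocount) / (early + pseudocount))
  trans <- association_transcripts(tree)
  det <- de[de$transcript_id %in% trans, , drop = FALSE]
  if (!is.null(comparison) && "comparison" %in% names(det))
    det <- det[det$comparison == comparison, , drop = FALSE]
  qmin <- if (nrow(det)) min(det$q_value) else Inf
  sig <- abs(l2fc) > log2fc_threshold && qmin < q_threshold
  list(log2fc = l2fc, fold_change = 2^abs(l2fc), significant = sig,
       reason = if (sig) NA_character_ else "below threshold")
}

#' Reactions eligible for flux-bound mutation
#'
#' Scans two timepoint comparisons for reaction-level differential
#' expression events with fold change at or above `fold_threshold` and a
#' significant transcript q-value, and assigns each eligible reaction an
#' intervention direction: down-regulated reactions are candidates for
#' flux *constraint*, up-regulated ones for flux *forcing*. Events from
#' the two comparisons are combined by union by default; when a reaction
#' moves in opposite directions in the two comparisons, the comparison
#' with the larger `|log2FC|` wins and an exact tie drops the reaction.
#'
#' @param model a `metabolic_model`.
#' @param profiles named list of TPM vectors keyed by timepoint label
#'   (needs the three labels referenced by `comparisons`).
#' @param de differential-expression table (see [reaction_differential()]).
#' @param comparisons character vector of two `"Ta-Tb"` tokens.
#' @param fold_threshold minimum reaction-level fold change (default 2).
#' @param mode `"union"` (default) or `"intersection"` of the two
#'   comparisons' events.
#' @param ... thresholds forwarded to [reaction_differential()].
#' @return data.frame with `reaction_id`, `direction` (`"constrain"` /
#'   `"force"`), `fold_change`, `log2fc`, `comparison`.
#' @export
eligible_reactions <- function(model, profiles, de,
                               comparisons = c("T1-T2", "T2-T3"),
                               fold_threshold = 2,
                               mode = c("union", "intersection"), ...) {
  mode <- match.arg(mode)
  events <- list()
  for (cmp in comparisons) {
    tps <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    if (!all(tps %in% names(profiles)))
      stop("profiles missing timepoint(s) for comparison ", cmp)
    for (i in seq_len(nrow(model$reactions))) {
      rid <- model$reactions$reaction_id[i]
      tree <- model$associations[[i]]
      if (is.null(tree)) next
      d <- reaction_differential(tree, de, profiles[[tps[1]]],
                                 profiles[[tps[2]]], comparison = cmp, ...)
      if (!isTRUE(d$significant)) next
      if (d$fold_change < fold_threshold) next
      events[[length(events) + 1L]] <- data.frame(
        reaction_id = rid,
        direction = if (d$log2fc < 0) "constrain" else "force",
        fold_change = d$fold_change,
        log2fc = d$log2fc,
        comparison = cmp,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(events))
    return(data.frame(reaction_id = character(0), direction = character(0),
                      fold_change = numeric(0), log2fc = numeric(0),
                      comparison = character(0), stringsAsFactors = FALSE))
  ev <- do.call(rbind, events)
  if (mode == "intersection") {
    keep <- names(which(table(ev$reaction_id) == length(comparisons)))
    ev <- ev[ev$reaction_id %in% keep, , drop = FALSE]
  }
  out <- lapply(split(ev, ev$reaction_id), function(g) {
    if (length(unique(g$direction)) > 1L) {
      mags <- abs(g$log2fc)
      if (abs(diff(range(mags))) < 1e-12) return(NULL)  # tie: ineligible
      g <- g[which.max(mags), , drop = FALSE]
    } else {
      g <- g[which.max(abs(g$log2fc)), , drop = FALSE]
    }
    g
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(reaction_id = character(0), direction = character(0),
                      fold_change = numeric(0), log2fc = numeric(0),
                      comparison = character(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$reaction_id), , drop = FALSE]
}

#' Read a wide expression table
#'
#' Tab-separated with `transcript_id` and one `tpm_<timepoint>` column per
#' timepoint, e.g. `tpm_T1  tpm_T2  tpm_T3`.
#'
#' @param path file path.
#' @return named list of TPM vectors keyed by timepoint label.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tpcols <- grep("^tpm_", names(df), value = TRUE)
  if (!length(tpcols)) stop("no tpm_<timepoint> columns in ", path)
  out <- lapply(tpcols, function(cn) setNames(df[[cn]], df$transcript_id))
  names(out) <- sub("^tpm_", "", tpcols)
  out
}

#' Write a wide expression table
#' @param profiles named list of TPM vectors keyed by timepoint.
#' @param path output path.
#' @export
write_expression_tsv <- function(profiles, path) {
  ids <- sort(unique(unlist(lapply(profiles, names))))
  df <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (tp in names(profiles))
    df[[paste0("tpm_", tp)]] <- unname(profiles[[tp]][ids])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with columns
#' `transcript_id  comparison  log2FC  q_value`; comparison tokens are
#' `"T1-T2"`-style ordered pairs.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_de_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "comparison", "log2FC", "q_value")
  if (!all(req %in% names(df)))
    stop("DE table must have columns: ", paste(req, collapse = ", "))
  if (any(df$q_value < 0 | df$q_value > 1))
    stop("q_value outside [0, 1] in ", path)
  df
}

#' Write a differential-expression table
#' @param de DE data.frame.
#' @param path output path.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
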