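# qPCR relative quantification: ddCt normalized to a reference gene
# (beta-actin by default), fold changes vs a control group, and circadian
# peak/trough timing.

# validate a well table (sample_id, group, gene, replicate, ct)
check_wells <- function(wells) {
  need <- c("sample_id", "gene", "ct")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("qPCR table lacks column(s): ", paste(miss, collapse = ", "))
  wells$ct <- as.numeric(wells$ct)
  if (anyNA(wells$ct) || any(wells$ct <= 0) || any(wells$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  if (is.null(wells$group)) wells$group <- "unspecified"
  wells$sample_id <- as.character(wells$sample_id)
  wells$gene <- as.character(wells$gene)
  wells$group <- as.character(wells$group)
  wells
}

#' Relative expression by the ddCt method
#'
#' Technical replicates are averaged on the Ct scale; for each sample and
#' target gene, `delta_ct = mean Ct_target - mean Ct_reference` and
#' `rel_expr = 2^-delta_ct`, with amplification efficiency fixed at 2 per
#' cycle (configurable). A uniform shift of all Ct values leaves every result
#' unchanged. Samples lacking the reference gene are dropped with a warning.
#'
#' @param wells data.frame of qPCR wells with columns `sample_id`, `gene`,
#'   `ct` and optionally `group` and `replicate`.
#' @param reference_gene the normalization gene (default `"beta-actin"`).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return data.frame with one row per sample x target gene: `sample_id`,
#'   `group`, `gene`, `delta_ct`, `rel_expr`.
#' @export
#' @examples
#' wells <- data.frame(sample_id = "s1", gene = c("sst1b", "beta-actin"),
#'                     ct = c(25, 20))
#' relative_expression(wells)$rel_expr  # 2^-5
relative_expression <- function(wells, reference_gene = "beta-actin",
                                efficiency = 2) {
  wells <- check_wells(wells)
  stopifnot(efficiency > 1)
  if (!reference_gene %in% wells$gene)
    stop("reference gene '", reference_gene, "' absent from the well table")
  mct <- aggregate(wells["ct"],
                   wells[c("sample_id", "group", "gene")], mean)
  ref <- mct[mct$gene == reference_gene, ]
  tgt <- mct[mct$gene != reference_gene, ]
  if (nrow(tgt) == 0) stop("no target genes beside the reference")
  i <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(i)) {
    dropped <- unique(tgt$sample_id[is.na(i)])
    warning("dropping sample(s) without reference gene: ",
            paste(dropped, collapse = ", "))
    tgt <- tgt[!is.na(i), ]
    i <- i[!is.na(i)]
  }
  out <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                    gene = tgt$gene, delta_ct = tgt$ct - ref$ct[i])
  out$rel_expr <- efficiency^(-out$delta_ct)
  out <- out[order(out$gene, out$group, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Fold change relative to a control group
#'
#' Per gene, each sample's relative expression divided by the geometric mean
#' of the control group's relative expression, so the control group has
#' geometric-mean fold 1 by construction and folds are invariant to any
#' global Ct offset.
#'
#' @param rel a [relative_expression()] table.
#' @param control_group label of the reference group (e.g. the wild type).
#' @return `rel` with an added `fold_change` column.
#' @export
fold_change <- function(rel, control_group) {
  stopifnot(is.data.frame(rel),
            all(c("group", "gene", "rel_expr") %in% names(rel)))
  if (!control_group %in% rel$group)
    stop("control group '", control_group, "' absent (or empty)")
  out <- do.call(rbind, lapply(split(rel, rel$gene), function(d) {
    ctrl <- d$rel_expr[d$group == control_group]
    if (length(ctrl) == 0)
      stop("control group '", control_group, "' empty for gene ", d$gene[1])
    d$fold_change <- d$rel_expr / exp(mean(log(ctrl)))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Per-group expression summary
#'
#' @param rel a [relative_expression()] (optionally [fold_change()]) table.
#' @return data.frame per gene x group with the mean, SEM and n of
#'   `rel_expr` (and of `fold_change` when present).
#' @export
expression_summary <- function(rel) {
  stopifnot(is.data.frame(rel), all(c("group", "gene") %in% names(rel)))
  cols <- intersect(c("rel_expr", "fold_change"), names(rel))
  out <- aggregate(rel[cols], rel[c("gene", "group")], function(v)
    c(mean = mean(v), sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                            else 0, n = length(v)))
  do.call(data.frame, out)
}

#' Peak and trough timing of a sampled circadian series
#'
#' Extrema are taken over the raw sampled timepoints (no smoothing): the peak
#' is the argmax, the trough the argmin. Ties are broken to the earliest time
#' and flagged; a constant series has no extremum and is flagged as such.
#' Adding a constant to the series shifts neither peak nor trough.
#'
#' @param time_h sampling times (zeitgeber or circadian hours), >= 3 points.
#' @param value measurement at each timepoint (e.g. relative mRNA level).
#' @return list of class `"circadian_extrema"`: `peak_time`, `trough_time`,
#'   `peak_value`, `trough_value`, `flag` (`NA`, `"tie"` or
#'   `"no_extremum"`).
#' @export
circadian_extrema <- function(time_h, value) {
  time_h <- as.numeric(time_h); value <- as.numeric(value)
  stopifnot(length(time_h) == length(value))
  if (length(time_h) < 3) stop("need at least 3 timepoints")
  if (anyNA(time_h) || anyNA(value)) stop("inputs must be finite")
  o <- order(time_h)
  time_h <- time_h[o]; value <- value[o]
  if (max(value) == min(value))
    return(structure(list(peak_time = NA_real_, trough_time = NA_real_,
                          peak_value = NA_real_, trough_value = NA_real_,
                          flag = "no_extremum"),
                     class = "circadian_extrema"))
  ip <- which(value == max(value)); it <- which(value == min(value))
  flag <- if (length(ip) > 1 || length(it) > 1) "tie" else NA_character_
  structure(list(peak_time = time_h[ip[1]], trough_time = time_h[it[1]],
                 peak_value = value[ip[1]], trough_value = value[it[1]],
                 flag = flag),
            class = "circadian_extrema")
}

#' Read / write qPCR well tables
#'
#' CSV with columns `sample_id`, `group`, `gene`, `replicate`, `ct`.
#'
#' @param path file path.
#' @param wells well data.frame to write.
#' @return `read_qpcr()` the validated well table; `write_qpcr()` `path`,
#'   invisibly.
#' @rdname qpcr_io
#' @export
read_qpcr <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(check_wells(d),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e))))
}

#' @rdname qpcr_io
#' @export
write_qpcr <- function(wells, path) {
  utils::write.csv(check_wells(wells), path, row.names = FALSE)
  invisible(path)
}
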