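as_interval <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, ])
  if (is.list(x)) x <- c(x$start, x$end)
  x <- as.numeric(x[1:2])
  if (anyNA(x) || x[1] < 1 || x[2] < x[1]) {
    stop("invalid interval: expected 1-based inclusive (start, end) with start <= end")
  }
  x
}

interval_length <- function(x) {
  x <- as_interval(x)
  x[2] - x[1] + 1
}

#' Overlap fraction between two residue intervals
#'
#' The fraction of the shorter interval covered by the intersection,
#' `|a : b| / min(|a|, |b|)` with 1-based inclusive lengths; 0 for disjoint
#' intervals. This is the quantity a predicted/experimental NoLS pair must
#' bring to at least 0.6 to count as a correct prediction. Symmetric, and
#' equal to 1 whenever one interval contains the other.
#'
#' @param a,b intervals as length-2 numeric vectors `c(start, end)`, lists,
#'   or one-row data frames with `start`/`end` columns.
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' overlap_fraction(c(129, 143), c(120, 143))  # 1.0: prediction contains it
#' overlap_fraction(c(31, 64), c(27, 49))      # 19/23
overlap_fraction <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  inter <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  if (inter <= 0) return(0)
  inter / min(a[2] - a[1] + 1, b[2] - b[1] + 1)
}

#' Length filter for experimental NoLSs admitted to evaluation
#'
#' Only short, confidently mapped experimental NoLSs are used for testing;
#' longer regions are more likely to be imprecisely mapped or to represent
#' signal patches assembled in the folded structure. The default keeps
#' intervals of inclusive length up to 50 residues (the benchmark's longest
#' retained NoLS spans exactly 50); `strict_length_filter` switches to a
#' strict `<` comparison.
#'
#' @param interval an interval (see [overlap_fraction()] for accepted forms).
#' @param params a [nols_params()].
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
length_filter <- function(interval, params = nols_params()) {
  len <- interval_length(interval)
  if (params$strict_length_filter) len < params$max_test_nols_length
  else len <= params$max_test_nols_length
}

#' One protein's evaluation record
#'
#' Pairs a protein's experimentally determined NoLS intervals with the
#' intervals a predictor called on it, plus organism/group labels.
#'
#' @param accession protein accession.
#' @param experimental data frame of `start`/`end` (1-based inclusive);
#'   must be non-empty.
#' @param predicted data frame of `start`/`end`; may have zero rows.
#' @param organism free-text organism name.
#' @param group taxon/host group label used for aggregation.
#' @param species finer species label (optional, used for per-species rows).
#' @param protein protein name (optional).
#' @return An object of class `evaluation_record`.
#' @export
evaluation_record <- function(accession, experimental, predicted,
                              organism = "", group = "", species = "",
                              protein = "") {
  stopifnot(is.data.frame(experimental), nrow(experimental) >= 1L,
            is.data.frame(predicted))
  for (i in seq_len(nrow(experimental))) as_interval(experimental[i, ])
  for (i in seq_len(nrow(predicted))) as_interval(predicted[i, ])
  out <- list(accession = accession, protein = protein, organism = organism,
              group = group, species = species,
              experimental = experimental[, c("start", "end")],
              predicted = if (nrow(predicted)) predicted[, c("start", "end")]
                          else data.frame(start = integer(), end = integer()))
  class(out) <- "evaluation_record"
  out
}

#' Classify one record's intervals at an overlap threshold
#'
#' Matching is many-to-many: an experimental NoLS is *detected* if at least
#' one predicted interval reaches the overlap criterion against it, and a
#' predicted interval is a *true positive* if it reaches the criterion
#' against at least one experimental NoLS, else a *false positive*. No
#' one-to-one assignment is made.
#'
#' @param record an [evaluation_record()].
#' @param min_overlap minimum [overlap_fraction()] for a match.
#' @return List with `detected` (logical per experimental interval), `tp`
#'   (logical per predicted interval) and `has_false_positive`.
#' @export
classify_record <- function(record, min_overlap = 0.6) {
  stopifnot(inherits(record, "evaluation_record"),
            min_overlap > 0, min_overlap <= 1)
  ne <- nrow(record$experimental)
  np <- nrow(record$predicted)
  ov <- matrix(0, nrow = ne, ncol = np)
  if (np > 0) {
    for (i in seq_len(ne)) {
      for (j in seq_len(np)) {
        ov[i, j] <- overlap_fraction(record$experimental[i, ],
                                     record$predicted[j, ])
      }
    }
  }
  detected <- if (np > 0) apply(ov >= min_overlap, 1, any) else rep(FALSE, ne)
  tp <- if (np > 0) apply(ov >= min_overlap, 2, any) else logical(0)
  list(detected = detected, tp = tp, has_false_positive = any(!tp))
}

#' The published NoD multi-organism benchmark
#'
#' Experimentally determined NoLSs collated from the literature across
#' eukaryotes and viruses, paired with the intervals the original NoD
#' predictor called on the full-length proteins: 27 distinct proteins
#' carrying 31 experimental NoLSs, against which NoD produced 28 predicted
#' intervals. Group labels follow the published accuracy breakdown
#' (mammals, amoeba, molluscs, trypanosomes, plants; viruses by host).
#' Shipped as a plain tab-separated file
#' (`system.file("extdata", "nod_benchmark.tsv", package = "nolscan")`).
#'
#' @param path alternative TSV with the same columns.
#' @return List of [evaluation_record()] objects, one per protein.
#' @export
#' @examples
#' length(nod_benchmark())  # 27 proteins
nod_benchmark <- function(path = system.file("extdata", "nod_benchmark.tsv",
                                             package = "nolscan")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  parse_pred <- function(s) {
    s <- trimws(s)
    if (tolower(s) == "none" || !nzchar(s)) {
      return(data.frame(start = integer(), end = integer()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    data.frame(start = as.integer(vapply(parts, `[`, character(1), 1L)),
               end = as.integer(vapply(parts, `[`, character(1), 2L)))
  }
  recs <- lapply(split(tab, factor(tab$accession, levels = unique(tab$accession))),
                 function(rows) {
    pred <- do.call(rbind, lapply(rows$prediction, parse_pred))
    pred <- unique(pred)
    pred <- pred[order(pred$start), , drop = FALSE]
    evaluation_record(
      accession = rows$accession[1],
      experimental = data.frame(start = rows$nols_start, end = rows$nols_end),
      predicted = pred,
      organism = rows$organism[1], group = rows$group[1],
      species = rows$species[1], protein = rows$protein[1])
  })
  unname(recs)
}

metrics_row <- function(label, level, cls, records) {
  nols <- sum(vapply(cls, function(x) length(x$detected), integer(1)))
  tp <- sum(vapply(cls, function(x) sum(x$detected), integer(1)))
  npred <- sum(vapply(cls, function(x) length(x$tp), integer(1)))
  fp <- sum(vapply(cls, function(x) sum(!x$tp), integer(1)))
  clean <- sum(!vapply(cls, `[[`, logical(1), "has_false_positive"))
  data.frame(level = level, label = label,
             proteins = length(records), nols = nols,
             tp = tp, fp = fp,
             sensitivity = if (nols > 0) tp / nols else NA_real_,
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             specificity = clean / length(records),
             stringsAsFactors = FALSE)
}

#' Accuracy metrics per group and overall
#'
#' Aggregates per-record classifications into the benchmark's accuracy
#' table. For each group (and each species label, where present) and
#' overall it reports: distinct protein count, experimental NoLS count,
#' TP (detected experimental NoLSs), FP (predicted intervals matching no
#' experimental NoLS), sensitivity `TP / NoLS count`, positive predictive
#' value `TP / (TP + FP)` (`NA` when nothing was predicted), and
#' per-protein specificity: the fraction of proteins with zero
#' false-positive segments. Experimental NoLSs failing [length_filter()]
#' are excluded before matching. Metrics are invariant to record order.
#'
#' @param records list of [evaluation_record()] objects.
#' @param min_overlap minimum [overlap_fraction()] for a match.
#' @param params a [nols_params()].
#' @return A data frame of class `nols_metrics`, one row per group, per
#'   species and an `overall` row, with raw fractions. `print()` rounds
#'   group rows to 2 decimals and the overall row to integer percentages,
#'   mirroring the benchmark's presentation.
#' @export
#' @examples
#' m <- compute_metrics(nod_benchmark())
#' subset(m, level == "overall")
compute_metrics <- function(records, min_overlap = 0.6,
                            params = nols_params()) {
  stopifnot(length(records) > 0)
  records <- lapply(records, function(r) {
    keep <- vapply(seq_len(nrow(r$experimental)), function(i) {
      length_filter(r$experimental[i, ], params)
    }, logical(1))
    r$experimental <- r$experimental[keep, , drop = FALSE]
    r
  })
  records <- Filter(function(r) nrow(r$experimental) > 0, records)
  if (!length(records)) stop("no experimental NoLS passes the length filter")
  cls <- lapply(records, classify_record, min_overlap = min_overlap)

  groups <- vapply(records, `[[`, character(1), "group")
  species <- vapply(records, `[[`, character(1), "species")
  rows <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    rows[[length(rows) + 1L]] <- metrics_row(g, "group", cls[sel], records[sel])
    for (s in unique(species[sel])) {
      if (!nzchar(s)) next
      sub <- sel & species == s
      rows[[length(rows) + 1L]] <- metrics_row(s, "species", cls[sub],
                                               records[sub])
    }
  }
  rows[[length(rows) + 1L]] <- metrics_row("overall", "overall", cls, records)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nols_metrics", "data.frame")
  out
}

#' @export
print.nols_metrics <- function(x, ...) {
  shown <- as.data.frame(x)
  grp <- shown$level != "overall"
  for (col in c("sensitivity", "ppv", "specificity")) {
    shown[[col]] <- ifelse(grp, round(shown[[col]], 2),
                           round(100 * shown[[col]]))
  }
  shown$unit <- ifelse(grp, "fraction", "%")
  print.data.frame(shown, row.names = FALSE, ...)
  invisible(x)
}

#' Export a metrics table as TSV
#'
#' @param metrics a `nols_metrics` data frame from [compute_metrics()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(as.data.frame(metrics), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
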