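#' Define calendar periods
#'
#' @param labels Character period labels.
#' @param start_years,end_years Inclusive calendar bounds, same length.
#' @return `data.frame` `label,start_year,end_year`, ordered and checked
#'   for overlap.
#' @export
period_definition <- function(labels, start_years, end_years) {
  stopifnot(length(labels) == length(start_years),
            length(labels) == length(end_years),
            all(end_years >= start_years))
  o <- order(start_years)
  d <- data.frame(label = as.character(labels)[o],
                  start_year = as.integer(start_years)[o],
                  end_year = as.integer(end_years)[o])
  if (nrow(d) > 1L && any(d$start_year[-1] <= d$end_year[-nrow(d)]))
    stop("periods overlap")
  d
}

#' Default pollution-defined periods
#'
#' The four calendar periods framing the central-European acid-deposition
#' history: before (1900-1935), during (1971-1989) and after (1998-2005,
#' 2006-2011) the peak in atmospheric pollution. `pre` is the reference
#' level in all period models.
#'
#' @return `data.frame` from [period_definition()].
#' @export
default_periods <- function() {
  period_definition(c("pre", "pollution", "post1", "post2"),
                    c(1900, 1971, 1998, 2006),
                    c(1935, 1989, 2005, 2011))
}

#' Average per-tree series into periods
#'
#' Produces one value per tree and period, the unit of analysis for the
#' period mixed models. Annual series (`year` column) are averaged over
#' the years falling inside each period. Segment series (`start_year` and
#' `end_year` columns, e.g. isotope-derived parameters) are averaged with
#' weights equal to the number of segment years overlapping the period, so
#' a segment lying half inside a period counts half.
#'
#' @param data `data.frame` with `tree_id`, `value`, and either `year` or
#'   `start_year`/`end_year`.
#' @param periods `data.frame` from [period_definition()].
#' @return `data.frame` `tree_id,period,value,n` (`n` = years or total
#'   overlap weight contributing). Tree-period combinations with no
#'   overlap are absent.
#' @export
period_means <- function(data, periods) {
  segmented <- all(c("start_year", "end_year") %in% names(data))
  if (!segmented && !"year" %in% names(data))
    stop("data must have a 'year' or 'start_year'/'end_year' columns")
  out <- list()
  for (id in unique(data$tree_id)) {
    d <- data[data$tree_id == id & !is.na(data$value), , drop = FALSE]
    for (k in seq_len(nrow(periods))) {
      p0 <- periods$start_year[k]; p1 <- periods$end_year[k]
      if (segmented) {
        w <- pmax(0, pmin(d$end_year, p1) - pmax(d$start_year, p0) + 1)
        if (sum(w) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          tree_id = id, period = periods$label[k],
          value = sum(w * d$value) / sum(w), n = sum(w))
      } else {
        inside <- d$year >= p0 & d$year <= p1
        if (!any(inside)) next
        out[[length(out) + 1L]] <- data.frame(
          tree_id = id, period = periods$label[k],
          value = mean(d$value[inside]), n = sum(inside))
      }
    }
  }
  if (length(out) == 0L) stop("no tree-period overlap")
  res <- do.call(rbind, out)
  res$period <- factor(res$period, levels = periods$label)
  res
}
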