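# internal helpers shared across modules

# validate a tibble of 0-based half-open intervals; returns it invisibly
check_intervals <- function(x, arg = "intervals", need_id = FALSE) {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame", arg))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss)) {
    abort(sprintf("`%s` lacks column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (nrow(x) && any(x$start >= x$end)) {
    abort(sprintf("`%s` contains intervals with start >= end", arg))
  }
  if (need_id) {
    if (!"id" %in% names(x)) abort(sprintf("`%s` needs an `id` column", arg))
    if (anyDuplicated(x$id)) abort(sprintf("`%s` ids must be unique", arg))
  }
  invisible(x)
}

check_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("`genome` must be a named vector of chromosome lengths")
  }
  if (any(genome <= 0)) abort("chromosome lengths must be positive")
  invisible(genome)
}

# merge intervals into disjoint sorted intervals, per chromosome
reduce_intervals <- function(x) {
  check_intervals(x)
  if (!nrow(x)) return(tibble(chrom = character(), start = double(), end = double()))
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  out <- lapply(split(x[c("start", "end")], x$chrom), function(d) {
    s <- d$start; e <- d$end
    run_end <- cummax(e)
    new_run <- c(TRUE, s[-1] > run_end[-length(s)])
    grp <- cumsum(new_run)
    tibble(
      start = s[new_run],
      end = as.numeric(tapply(e, grp, max))
    )
  })
  dplyr::bind_rows(out, .id = "chrom") |> dplyr::arrange(.data$chrom, .data$start)
}

# derive a reproducible child seed (< 2^31) from a master seed and a tag
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%g0%` <- function(x, y) if (length(x)) x else y
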