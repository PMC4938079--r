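#' Read and write waveform files
#'
#' Waveforms travel as two-column delimited text (`time_s`, `value`) with
#' a header comment naming the quantity, unit and period, e.g.
#' `# pulsewave waveform quantity: pressure unit: mmHg period_s: 0.98`.
#' Values are converted to SI on read; `write_waveform()` writes clinical
#' units at full precision, so a write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_waveform()` returns a [waveform] (SI units).
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- paste(hdr, collapse = " ")
  get <- function(key) {
    m <- regmatches(meta, regexec(paste0(key, ":\\s*(\\S+)"), meta))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  quantity <- get("quantity")
  unit <- get("unit")
  period <- suppressWarnings(as.numeric(get("period_s")))
  if (is.na(quantity))
    stop("waveform file lacks a 'quantity:' header: ", path)
  if (is.na(unit))
    stop("waveform file lacks a 'unit:' header (no silent default): ", path)
  dat <- utils::read.table(path, comment.char = "#",
                           col.names = c("time_s", "value"))
  if (any(diff(dat$time_s) <= 0))
    stop("non-monotone time column in ", path)
  waveform(dat$time_s, to_si(dat$value, unit), quantity,
           period = if (is.na(period)) NULL else period)
}

#' @rdname read_waveform
#' @param w a [waveform].
#' @param unit output unit (default: the clinical unit of the quantity).
#' @export
write_waveform <- function(w, path, unit = clinical_unit_of(w$quantity)) {
  hdr <- sprintf(
    "# pulsewave waveform quantity: %s unit: %s period_s: %.17g",
    w$quantity, unit, w$period)
  body <- sprintf("%.17g\t%.17g", w$times, from_si(w$values, unit))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write segment tables
#'
#' Segment tables are tab-separated text with one row per segment. Two
#' dialects are accepted: plain columns (`r_in_mm`, `r_out_mm`, `c_in_ms`,
#' `c_out_ms`) or the arrow dialect in which paired inlet/outlet values
#' share a cell (`r_mm` = `"12.4 -> 13.2"`), as in printed vessel tables.
#' Both foot-to-foot (`cff_*`) and QA-loop (`cqa_*`) speed columns may be
#' present; `speeds` selects which populates `c_in`/`c_out`.
#'
#' @param path file path.
#' @param speeds `"foot_to_foot"` or `"qa_loop"` when both are present.
#' @return data.frame in the SI layout expected by [network()] (`length`,
#'   `r_in`, `r_out` in m, `c_in`, `c_out` in m/s), retaining any extra
#'   speed columns as `cff_in`/`cff_out`/`cqa_in`/`cqa_out` (m/s).
#' @export
read_segment_table <- function(path, speeds = c("foot_to_foot", "qa_loop")) {
  speeds <- match.arg(speeds)
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE)
  split_arrow <- function(col, row_label) {
    parts <- strsplit(gsub("→", "->", col), "->")
    bad <- which(vapply(parts, length, integer(1)) != 2)
    if (length(bad))
      stop("malformed arrow cell in row ", bad[1], " of ", row_label)
    list(as.numeric(trimws(vapply(parts, `[`, character(1), 1))),
         as.numeric(trimws(vapply(parts, `[`, character(1), 2))))
  }
  if (!"r_in_mm" %in% names(tab) && "r_mm" %in% names(tab)) {
    r <- split_arrow(tab$r_mm, "r_mm")
    tab$r_in_mm <- r[[1]]; tab$r_out_mm <- r[[2]]
  }
  for (pref in c("c", "cff", "cqa")) {
    a <- paste0(pref, "_ms")
    if (!paste0(pref, "_in_ms") %in% names(tab) && a %in% names(tab)) {
      v <- split_arrow(tab[[a]], a)
      tab[[paste0(pref, "_in_ms")]] <- v[[1]]
      tab[[paste0(pref, "_out_ms")]] <- v[[2]]
    }
  }
  if (!"c_in_ms" %in% names(tab)) {
    pick <- if (speeds == "foot_to_foot") "cff" else "cqa"
    if (!paste0(pick, "_in_ms") %in% names(tab))
      stop("segment table has no usable wave-speed columns")
    tab$c_in_ms <- tab[[paste0(pick, "_in_ms")]]
    tab$c_out_ms <- tab[[paste0(pick, "_out_ms")]]
  }
  need <- c("id", "name", "length_cm", "r_in_mm", "r_out_mm",
            "c_in_ms", "c_out_ms", "parent", "terminal")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    if (!is.finite(tab$length_cm[i]) || tab$length_cm[i] <= 0)
      stop("row ", i, " (", tab$name[i], "): non-positive length")
    if (tab$r_in_mm[i] <= 0 || tab$r_out_mm[i] <= 0)
      stop("row ", i, " (", tab$name[i], "): non-positive radius")
  }
  out <- data.frame(
    id = as.integer(tab$id), name = tab$name,
    length = tab$length_cm * 1e-2,
    r_in = tab$r_in_mm * 1e-3, r_out = tab$r_out_mm * 1e-3,
    c_in = tab$c_in_ms, c_out = tab$c_out_ms,
    parent = suppressWarnings(as.integer(tab$parent)),
    terminal = as.logical(tab$terminal)
  )
  for (pref in c("cff", "cqa")) {
    if (paste0(pref, "_in_ms") %in% names(tab)) {
      out[[paste0(pref, "_in")]] <- tab[[paste0(pref, "_in_ms")]]
      out[[paste0(pref, "_out")]] <- tab[[paste0(pref, "_out_ms")]]
    }
  }
  out
}

#' @rdname read_segment_table
#' @param segments data.frame in the layout returned by
#'   [read_segment_table()] (SI units), or the clinical layout of
#'   [upper_aorta_segments()].
#' @export
write_segment_table <- function(segments, path) {
  s <- segments
  cols <- list(id = s$id, name = s$name)
  if ("length" %in% names(s)) {        # SI layout -> clinical columns
    cols$length_cm <- s$length * 1e2
    cols$r_mm <- sprintf("%g -> %g", s$r_in * 1e3, s$r_out * 1e3)
    if ("cff_in" %in% names(s)) {
      cols$cff_ms <- sprintf("%g -> %g", s$cff_in, s$cff_out)
    } else {
      cols$c_ms <- sprintf("%g -> %g", s$c_in, s$c_out)
    }
    if ("cqa_in" %in% names(s))
      cols$cqa_ms <- sprintf("%g -> %g", s$cqa_in, s$cqa_out)
  } else {
    cols$length_cm <- s$length_cm
    cols$r_mm <- sprintf("%g -> %g", s$r_in_mm, s$r_out_mm)
    cols$cff_ms <- sprintf("%g -> %g", s$cff_in_ms, s$cff_out_ms)
    cols$cqa_ms <- sprintf("%g -> %g", s$cqa_in_ms, s$cqa_out_ms)
  }
  cols$parent <- s$parent
  cols$terminal <- s$terminal
  s <- as.data.frame(cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pulsewave segment table", con)
  utils::write.table(s, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
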