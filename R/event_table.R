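#' Flow-cytometry event table
#'
#' Container for one acquisition sample: an events-by-channels matrix of
#' intensities plus sample metadata. The five channels used throughout the
#' pipeline are `FSC.A`, `SSC.A`, `FSC.W` (forward/side scatter area and
#' forward-scatter pulse width), `DAPI` (DNA stain) and `FL` (the antibody
#' fluorescence channel, stored as log intensity).
#'
#' @param events data.frame (or matrix) of event intensities; must contain the
#'   columns listed in `channels`.
#' @param sample_id,line_id,protein identifiers of the sample, cell line and
#'   stained protein.
#' @param replicate integer replicate index within line x protein.
#' @param batch identifier of the experimental set; gates, saturation bounds
#'   and outlier-score pools are never shared across batches.
#' @param channels required channel names.
#' @return An object of class `event_table`: a data.frame of events with
#'   metadata attributes (`sample_id`, `line_id`, `protein`, `replicate`,
#'   `batch`).
#' @export
event_table <- function(events, sample_id, line_id = sample_id,
                        protein = "FL", replicate = 1L, batch = "set1",
                        channels = c("FSC.A", "SSC.A", "FSC.W", "DAPI", "FL")) {
  events <- as.data.frame(events)
  missing_ch <- setdiff(channels, names(events))
  if (length(missing_ch))
    stop("event_table: missing channel(s): ", paste(missing_ch, collapse = ", "))
  structure(events,
            sample_id = as.character(sample_id),
            line_id = as.character(line_id),
            protein = as.character(protein),
            replicate = as.integer(replicate),
            batch = as.character(batch),
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table '%s' (line %s, %s, replicate %d, batch %s): %d events x %d channels\n",
              attr(x, "sample_id"), attr(x, "line_id"), attr(x, "protein"),
              attr(x, "replicate"), attr(x, "batch"), nrow(x), ncol(x)))
  invisible(x)
}

#' Subset an event table by row, keeping metadata
#'
#' @param x event_table
#' @param keep logical or integer row index of events to retain
#' @return event_table with the same metadata
#' @export
subset_events <- function(x, keep) {
  meta <- attributes(x)[c("sample_id", "line_id", "protein", "replicate", "batch")]
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  do.call(event_table, c(list(events = out), meta,
                         list(channels = intersect(c("FSC.A","SSC.A","FSC.W","DAPI","FL"),
                                                   names(out)))))
}

meta_of <- function(x) {
  list(sample_id = attr(x, "sample_id"), line_id = attr(x, "line_id"),
       protein = attr(x, "protein"), replicate = attr(x, "replicate"),
       batch = attr(x, "batch"))
}

#' Write / read event tables as CSV plus a manifest
#'
#' One CSV file per sample; the manifest TSV records the file name and the
#' sample metadata so a directory round-trips losslessly.
#'
#' @param samples list of `event_table`
#' @param dir output directory (created if absent)
#' @return `write_event_csv` invisibly returns the manifest data.frame;
#'   `read_event_csv` returns a list of `event_table`.
#' @export
write_event_csv <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(seq_along(samples), function(i) {
    m <- meta_of(samples[[i]])
    file <- sprintf("%s.csv", m$sample_id)
    utils::write.csv(as.data.frame(samples[[i]]),
                     file.path(dir, file), row.names = FALSE)
    data.frame(file = file, sample_id = m$sample_id, line_id = m$line_id,
               protein = m$protein, replicate = m$replicate, batch = m$batch,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    ev <- utils::read.csv(file.path(dir, man$file[i]))
    event_table(ev, sample_id = man$sample_id[i], line_id = man$line_id[i],
                protein = man$protein[i], replicate = man$replicate[i],
                batch = man$batch[i])
  })
}
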