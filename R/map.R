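#' Construct a genetic map
#'
#' Marker positions in centimorgans, the coordinate system of the circos
#' layout.
#'
#' @param marker character marker identifiers (unique).
#' @param chromosome positive integer chromosome id per marker.
#' @param position_cM non-negative map position per marker.
#' @param chromosome_lengths optional named numeric vector (names =
#'   chromosome ids) of segment lengths in cM; defaults to the largest marker
#'   position per chromosome.
#' @return An object of class `genetic_map` with a `table` data frame and a
#'   `chromosome_lengths` vector.
#' @export
genetic_map <- function(marker, chromosome, position_cM,
                        chromosome_lengths = NULL) {
  marker <- as.character(marker)
  chromosome <- as.integer(chromosome)
  position_cM <- as.numeric(position_cM)
  if (anyDuplicated(marker)) stop("duplicate markers in map")
  if (any(chromosome < 1L)) stop("chromosome ids must be positive integers")
  if (any(position_cM < 0)) stop("map positions must be non-negative")
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- tapply(position_cM, chromosome, max)
  }
  chromosome_lengths <- chromosome_lengths[order(as.integer(names(chromosome_lengths)))]
  for (i in seq_along(marker)) {
    L <- chromosome_lengths[as.character(chromosome[i])]
    if (is.na(L) || position_cM[i] > L + 1e-9) {
      stop("marker ", marker[i], " lies beyond its chromosome length")
    }
  }
  tab <- data.frame(marker = marker, chromosome = chromosome,
                    position_cM = position_cM, stringsAsFactors = FALSE)
  structure(list(table = tab, chromosome_lengths = chromosome_lengths),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d markers on %d chromosomes (%.1f cM total)\n",
              nrow(x$table), length(x$chromosome_lengths),
              sum(x$chromosome_lengths)))
  invisible(x)
}

#' Read a genetic map TSV (`marker  chrom  pos_cM`)
#'
#' @param path TSV path with header.
#' @param chromosome_lengths optional, see [genetic_map()].
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, chromosome_lengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("marker", "chrom", "pos_cM")
  genetic_map(df$marker, df$chrom, df$pos_cM, chromosome_lengths)
}

#' Write a genetic map TSV
#' @param map a [genetic_map()].
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(
    data.frame(marker = map$table$marker, chrom = map$table$chromosome,
               pos_cM = map$table$position_cM),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

map_lookup <- function(map, markers) {
  i <- match(markers, map$table$marker)
  if (anyNA(i)) {
    stop("marker(s) missing from the genetic map: ",
         paste(markers[is.na(i)], collapse = ", "))
  }
  map$table[i, , drop = FALSE]
}

#' Construct an annotation track (known QTL / gene regions)
#'
#' @param track track name, e.g. "QTL", "SAM" or "leaf".
#' @param chromosome integer chromosome per region.
#' @param start_cM,end_cM region bounds in cM, `start_cM <= end_cM`.
#' @param label region label (gene or QTL name).
#' @param pathway optional pathway tag.
#' @param map optional [genetic_map()] used to validate chromosomes.
#' @return An object of class `annotation_track` (a data frame).
#' @export
annotation_track <- function(track, chromosome, start_cM, end_cM, label,
                             pathway = NA_character_, map = NULL) {
  if (any(start_cM > end_cM)) stop("annotation regions need start <= end")
  df <- data.frame(track = track, chromosome = as.integer(chromosome),
                   start_cM = as.numeric(start_cM), end_cM = as.numeric(end_cM),
                   label = as.character(label),
                   pathway = as.character(pathway), stringsAsFactors = FALSE)
  if (!is.null(map)) {
    bad <- setdiff(df$chromosome, as.integer(names(map$chromosome_lengths)))
    if (length(bad)) stop("annotation chromosome(s) not in map: ",
                          paste(bad, collapse = ", "))
  }
  class(df) <- c("annotation_track", class(df))
  df
}

#' Read annotation regions from TSV
#'
#' Columns: `track  chrom  start_cM  end_cM  label  pathway`.
#'
#' @param path TSV path with header.
#' @param map optional [genetic_map()] for validation.
#' @return A list of [annotation_track()] objects, one per distinct track.
#' @export
read_annotations <- function(path, map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("track", "chrom", "start_cM", "end_cM", "label", "pathway")
  lapply(split(df, df$track), function(s) {
    annotation_track(s$track, s$chrom, s$start_cM, s$end_cM, s$label,
                     s$pathway, map)
  })
}
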