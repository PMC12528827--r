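#' Decile levels of marker-effect strength
#'
#' Markers are ranked by effect magnitude and partitioned into 10 quantile
#' bins; level 10 holds the strongest effects. Tied scores share the level of
#' their average rank. With `P` distinct scores every level holds between
#' `floor(P/10)` and `ceiling(P/10)` markers.
#'
#' @param effects named numeric scores (or a [gp_effects()]).
#' @return Named integer vector of levels in 1..10.
#' @export
decile_bins <- function(effects) {
  if (inherits(effects, "gp_effects")) effects <- effects$scores
  if (!length(effects)) stop("no markers")
  r <- rank(abs(effects), ties.method = "average")
  lev <- as.integer(ceiling(10 * r / length(effects)))
  lev[lev < 1L] <- 1L
  stats::setNames(lev, names(effects))
}

#' Extend marker positions into displayable regions
#'
#' Each marker's point position is widened by `pad_cM` on each side and
#' clipped to its chromosome's bounds.
#'
#' @param map a [genetic_map()].
#' @param markers marker names (must exist in the map).
#' @param pad_cM padding in cM (default 0.2).
#' @return Data frame `marker, chromosome, start_cM, end_cM`.
#' @export
extend_regions <- function(map, markers, pad_cM = 0.2) {
  tab <- map_lookup(map, markers)
  L <- map$chromosome_lengths[as.character(tab$chromosome)]
  data.frame(marker = tab$marker, chromosome = tab$chromosome,
             start_cM = pmax(0, tab$position_cM - pad_cM),
             end_cM = pmin(as.numeric(L), tab$position_cM + pad_cM),
             stringsAsFactors = FALSE)
}

#' Select the strongest marker-by-marker interaction links
#'
#' Keeps the `k = max(1, ceiling(fraction * P(P-1)/2))` unordered pairs with
#' the largest interaction magnitude (the published display keeps the top
#' 0.01%); zero-strength links are suppressed. Link class is `within` or
#' `between` by chromosome equality when a map is supplied.
#'
#' @param m symmetric interaction matrix (markers x markers).
#' @param fraction fraction of all pairs to keep (default 1e-4).
#' @param map optional [genetic_map()] for endpoint coordinates and class.
#' @return Data frame of class `gp_linkset`:
#'   `marker_a, marker_b, strength, class` plus coordinates when mapped.
#' @export
select_top_interactions <- function(m, fraction = 0.0001, map = NULL) {
  P <- nrow(m)
  if (P < 2L) stop("need at least 2 markers for interactions")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(marker_a = rownames(m)[idx[, 1L]],
                   marker_b = colnames(m)[idx[, 2L]],
                   strength = abs(m[idx]), stringsAsFactors = FALSE)
  k <- max(1L, ceiling(fraction * nrow(df)))
  df <- df[order(-df$strength, df$marker_a, df$marker_b), , drop = FALSE]
  df <- utils::head(df, k)
  df <- df[df$strength > 0, , drop = FALSE]
  df$class <- rep(NA_character_, nrow(df))
  if (!is.null(map) && nrow(df)) {
    ta <- map_lookup(map, df$marker_a)
    tb <- map_lookup(map, df$marker_b)
    df$chrom_a <- ta$chromosome; df$pos_a <- ta$position_cM
    df$chrom_b <- tb$chromosome; df$pos_b <- tb$position_cM
    df$class <- ifelse(df$chrom_a == df$chrom_b, "within", "between")
  }
  rownames(df) <- NULL
  class(df) <- c("gp_linkset", class(df))
  df
}

#' Build the layered circos layout
#'
#' One segment per chromosome (lengths in cM) and a fixed ring order,
#' innermost to outermost: annotation tracks (QTL, SAM, leaf), the six model
#' rings (GAT, SVR, RF, RKHS, BayesB, rrBLUP), then the ensemble ring.
#' Model/ensemble rings shade each (padded) marker region by the decile of
#' its aggregated effect magnitude.
#'
#' @param map a [genetic_map()].
#' @param annotations list of [annotation_track()]s (innermost rings).
#' @param model_effects named list of per-model aggregated scores (named
#'   numeric vectors or [gp_effects()]); reordered to the canonical ring
#'   order for the models present.
#' @param ensemble_effect aggregated ensemble scores (outermost ring).
#' @param pad_cM marker region padding (default 0.2).
#' @return List of class `gp_circos_layout` with `segments` and `rings`.
#' @export
build_layout <- function(map, annotations = list(), model_effects = list(),
                         ensemble_effect = NULL, pad_cM = 0.2) {
  chroms <- as.integer(names(map$chromosome_lengths))
  rings <- list()
  ann_order <- c("QTL", "SAM", "leaf")
  nm <- vapply(annotations, function(a) a$track[1L], "")
  for (a in annotations[order(match(nm, ann_order, nomatch = 99L))]) {
    bad <- setdiff(unique(a$chromosome), chroms)
    if (length(bad)) stop("annotation chromosome(s) not in map: ",
                          paste(bad, collapse = ", "))
    rings[[length(rings) + 1L]] <- list(
      name = a$track[1L], role = "annotation",
      cells = data.frame(chromosome = a$chromosome, start_cM = a$start_cM,
                         end_cM = a$end_cM, level_or_label = a$label,
                         stringsAsFactors = FALSE))
  }
  model_order <- c("GAT", "SVR", "RF", "RKHS", "BayesB", "rrBLUP")
  present <- intersect(model_order, names(model_effects))
  extra <- setdiff(names(model_effects), model_order)
  effect_ring <- function(name, scores, role) {
    if (inherits(scores, "gp_effects")) scores <- scores$scores
    scores <- scores[is.finite(scores)]
    lev <- decile_bins(scores)
    reg <- extend_regions(map, names(scores), pad_cM)
    list(name = name, role = role,
         cells = data.frame(chromosome = reg$chromosome,
                            start_cM = reg$start_cM, end_cM = reg$end_cM,
                            level_or_label = as.character(lev),
                            stringsAsFactors = FALSE))
  }
  for (mod in c(present, extra)) {
    rings[[length(rings) + 1L]] <- effect_ring(mod, model_effects[[mod]],
                                               "model")
  }
  if (!is.null(ensemble_effect)) {
    rings[[length(rings) + 1L]] <- effect_ring("Ensemble", ensemble_effect,
                                               "ensemble")
  }
  structure(list(segments = map$chromosome_lengths, rings = rings),
            class = "gp_circos_layout")
}

#' @export
print.gp_circos_layout <- function(x, ...) {
  cat(sprintf("gp_circos_layout: %d segments, %d rings (%s)\n",
              length(x$segments), length(x$rings),
              paste(vapply(x$rings, `[[`, "", "name"), collapse = " < ")))
  invisible(x)
}

# 10-step monotone-luminance ramps; indices 1..10 = weakest..strongest
ring_palette <- function(role, track = "") {
  switch(role,
         model = grDevices::colorRampPalette(c("#E8F0FB", "#08306B"))(10),
         ensemble = grDevices::colorRampPalette(c("#FEEDDE", "#7F2704"))(10),
         annotation = switch(track, QTL = "#666666", SAM = "#2C944C",
                             leaf = "#8C5BA8", "#B8860B"))
}

segment_geometry <- function(segments, gap_deg = 2) {
  n <- length(segments)
  total <- sum(segments)
  avail <- 360 - gap_deg * n
  start <- numeric(n)
  ang <- avail * segments / total
  cur <- 90  # start at 12 o'clock, clockwise
  for (i in seq_len(n)) {
    start[i] <- cur
    cur <- cur - ang[i] - gap_deg
  }
  list(start_deg = stats::setNames(start, names(segments)),
       deg_per_cM = stats::setNames(ang / segments, names(segments)))
}

pos_to_angle <- function(geom, chrom, pos) {
  ch <- as.character(chrom)
  (geom$start_deg[ch] - geom$deg_per_cM[ch] * pos) * pi / 180
}

draw_circos <- function(layout, links = NULL, r_inner = 0.35, r_outer = 0.95) {
  graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  graphics::plot.new()
  graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
  geom <- segment_geometry(layout$segments)
  nr <- length(layout$rings)
  band <- (r_outer - r_inner) / max(nr, 1L)
  arc <- function(r0, r1, th0, th1, col, border = NA) {
    th <- seq(th0, th1, length.out = max(2L, ceiling(abs(th1 - th0) * 60)))
    graphics::polygon(c(r0 * cos(th), r1 * cos(rev(th))),
                      c(r0 * sin(th), r1 * sin(rev(th))),
                      col = col, border = border, lwd = 0.3)
  }
  # chromosome backbone + labels
  for (ch in names(layout$segments)) {
    th0 <- pos_to_angle(geom, ch, 0)
    th1 <- pos_to_angle(geom, ch, layout$segments[[ch]])
    arc(r_outer + 0.02, r_outer + 0.05, th0, th1, "#BBBBBB", "#888888")
    thm <- (th0 + th1) / 2
    graphics::text(1.08 * cos(thm), 1.08 * sin(thm), ch, cex = 0.8)
  }
  for (i in seq_along(layout$rings)) {
    ring <- layout$rings[[i]]
    r0 <- r_inner + (i - 1L) * band
    r1 <- r0 + band * 0.85
    pal <- ring_palette(ring$role, ring$name)
    for (ch in names(layout$segments)) {   # faint ring guide
      arc(r0, r1, pos_to_angle(geom, ch, 0),
          pos_to_angle(geom, ch, layout$segments[[ch]]), "#F7F7F7")
    }
    cells <- ring$cells
    for (j in seq_len(nrow(cells))) {
      col <- if (ring$role == "annotation") pal else
        pal[as.integer(cells$level_or_label[j])]
      arc(r0, r1, pos_to_angle(geom, cells$chromosome[j], cells$start_cM[j]),
          pos_to_angle(geom, cells$chromosome[j], cells$end_cM[j]), col)
    }
  }
  if (!is.null(links) && nrow(links)) {
    smax <- max(links$strength)
    for (j in seq_len(nrow(links))) {
      tha <- pos_to_angle(geom, links$chrom_a[j], links$pos_a[j])
      thb <- pos_to_angle(geom, links$chrom_b[j], links$pos_b[j])
      r <- r_inner - 0.02
      t <- seq(0, 1, length.out = 50)
      # quadratic Bezier through the centre
      bx <- (1 - t)^2 * r * cos(tha) + t^2 * r * cos(thb)
      by <- (1 - t)^2 * r * sin(tha) + t^2 * r * sin(thb)
      graphics::lines(bx, by,
                      col = if (links$class[j] == "within") "#CC3333" else
                        "#3355CC",
                      lwd = 0.5 + 2.5 * links$strength[j] / smax)
    }
  }
  invisible(NULL)
}

#' Render the circos plot and its plain-data exports
#'
#' Writes `<out>.svg` and `<out>.png` plus two diffable TSVs:
#' `<out>_tracks.tsv` (`ring  chrom  start_cM  end_cM  level_or_label`, with
#' one `segments` row per chromosome) and `<out>_links.tsv`
#' (`chrom_a  pos_a  chrom_b  pos_b  strength  class`).
#'
#' @param layout a [build_layout()] result.
#' @param links optional [select_top_interactions()] result (mapped).
#' @param out output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
render_circos <- function(layout, links = NULL, out = "circos") {
  dir <- dirname(out)
  if (!dir.exists(dir)) stop("unwritable output path: ", dir)
  files <- character(0)

  track_rows <- do.call(rbind, c(
    list(data.frame(ring = "segments", chrom = names(layout$segments),
                    start_cM = 0, end_cM = as.numeric(layout$segments),
                    level_or_label = "segment", stringsAsFactors = FALSE)),
    lapply(layout$rings, function(rg) {
      data.frame(ring = rg$name, chrom = rg$cells$chromosome,
                 start_cM = rg$cells$start_cM, end_cM = rg$cells$end_cM,
                 level_or_label = rg$cells$level_or_label,
                 stringsAsFactors = FALSE)
    })))
  f <- paste0(out, "_tracks.tsv")
  utils::write.table(track_rows, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- paste0(out, "_links.tsv")
  if (!is.null(links) && nrow(links)) {
    utils::write.table(links[, c("chrom_a", "pos_a", "chrom_b", "pos_b",
                                 "strength", "class")],
                       f, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(
      data.frame(chrom_a = integer(0), pos_a = numeric(0),
                 chrom_b = integer(0), pos_b = numeric(0),
                 strength = numeric(0), class = character(0)),
      f, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  files <- c(files, f)

  for (ext in c("svg", "png")) {
    fp <- paste0(out, ".", ext)
    ok <- tryCatch({
      if (ext == "svg") grDevices::svg(fp, width = 7, height = 7) else
        grDevices::png(fp, width = 1400, height = 1400, res = 200)
      draw_circos(layout, links)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("could not render ", ext, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) files <- c(files, fp)
  }
  invisible(files)
}

#' Re-read a circos track export
#'
#' Parses the `<out>_tracks.tsv` written by [render_circos()] back into a
#' `gp_circos_layout` (segments plus ring cells; palette roles are restored
#' from the canonical ring names).
#'
#' @param path tracks TSV path.
#' @return A `gp_circos_layout`.
#' @export
read_layout_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(level_or_label = "character"))
  seg <- df[df$ring == "segments", ]
  segments <- stats::setNames(seg$end_cM, seg$chrom)
  rest <- df[df$ring != "segments", ]
  rings <- lapply(unique(rest$ring), function(nm) {
    s <- rest[rest$ring == nm, ]
    role <- if (nm == "Ensemble") "ensemble" else
      if (nm %in% c("GAT", "SVR", "RF", "RKHS", "BayesB", "rrBLUP")) "model"
      else "annotation"
    list(name = nm, role = role,
         cells = data.frame(chromosome = s$chrom, start_cM = s$start_cM,
                            end_cM = s$end_cM,
                            level_or_label = s$level_or_label,
                            stringsAsFactors = FALSE))
  })
  structure(list(segments = segments, rings = rings),
            class = "gp_circos_layout")
}
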