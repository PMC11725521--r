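#' Canonicalize assembly-graph links
#'
#' Every GFA link has an equivalent complement obtained by swapping its
#' endpoints and flipping both orientations (traversing the junction from the
#' other side). Each link is replaced by the lexicographically smaller of the
#' two forms, and duplicates (including complement pairs) are collapsed.
#'
#' @param links Tibble with columns `from_id`, `from_orient`, `to_id`,
#'   `to_orient` and optionally `overlap`.
#' @return The canonicalized, de-duplicated link tibble.
#' @export
canonicalize_links <- function(links) {
  if (!nrow(links)) return(links)
  comp <- tibble::tibble(
    from_id = links$to_id,
    from_orient = flip_orient(links$to_orient),
    to_id = links$from_id,
    to_orient = flip_orient(links$from_orient)
  )
  orig_key <- paste(links$from_id, links$from_orient, links$to_id, links$to_orient, sep = "\r")
  comp_key <- paste(comp$from_id, comp$from_orient, comp$to_id, comp$to_orient, sep = "\r")
  take_comp <- comp_key < orig_key
  out <- links
  out$from_id <- ifelse(take_comp, comp$from_id, links$from_id)
  out$from_orient <- ifelse(take_comp, comp$from_orient, links$from_orient)
  out$to_id <- ifelse(take_comp, comp$to_id, links$to_id)
  out$to_orient <- ifelse(take_comp, comp$to_orient, links$to_orient)
  dplyr::distinct(out, .data$from_id, .data$from_orient, .data$to_id,
                  .data$to_orient, .keep_all = TRUE)
}

segment_lengths <- function(segments) {
  len <- segments$length
  miss <- is.na(len) & !is.na(segments$seq)
  len[miss] <- nchar(segments$seq[miss])
  len
}

# Oriented adjacency moves implied by canonical links: each link allows
# (from, fo) -> (to, to_orient) and (to, !to_orient) -> (from, !fo).
link_moves <- function(links) {
  fwd <- tibble::tibble(
    a = links$from_id, ao = links$from_orient,
    b = links$to_id, bo = links$to_orient,
    overlap = links$overlap %||% rep(0L, nrow(links)),
    link = seq_len(nrow(links))
  )
  rev <- tibble::tibble(
    a = links$to_id, ao = flip_orient(links$to_orient),
    b = links$from_id, bo = flip_orient(links$from_orient),
    overlap = fwd$overlap, link = fwd$link
  )
  dplyr::bind_rows(fwd, rev)
}

# Find the closed walk LSC -> IR -> SSC -> revcomp(IR) -> LSC using 4 distinct
# links; returns a 4-row tibble (seg, orient, overlap to the next step) or NULL.
find_quadripartite_walk <- function(links, lsc, ssc, ir) {
  moves <- link_moves(links)
  step_from <- function(a, ao, b) {
    dplyr::filter(moves, .data$a == !!a, .data$ao == !!ao, .data$b == !!b)
  }
  for (o1 in c("+", "-")) {
    m1 <- step_from(lsc, o1, ir)
    for (i in seq_len(nrow(m1))) {
      o2 <- m1$bo[i]
      m2 <- step_from(ir, o2, ssc)
      for (j in seq_len(nrow(m2))) {
        o3 <- m2$bo[j]
        o4 <- flip_orient(o2) # second IR pass traverses the reverse complement
        m3 <- step_from(ssc, o3, ir)
        m3 <- m3[m3$bo == o4, , drop = FALSE]
        for (l in seq_len(nrow(m3))) {
          m4 <- step_from(ir, o4, lsc)
          m4 <- m4[m4$bo == o1, , drop = FALSE]
          for (w in seq_len(nrow(m4))) {
            used <- c(m1$link[i], m2$link[j], m3$link[l], m4$link[w])
            if (length(unique(used)) == 4) {
              return(tibble::tibble(
                seg = c(lsc, ir, ssc, ir),
                orient = c(o1, o2, o3, o4),
                overlap = c(m1$overlap[i], m2$overlap[j], m3$overlap[l], m4$overlap[w])
              ))
            }
          }
        }
      }
    }
  }
  NULL
}

#' Classify assembly-graph topology
#'
#' Recognizes the typical quadripartite chloroplast structure — three
#' segments (large single copy, small single copy, inverted repeat) with four
#' links in which the IR is traversed twice in opposite orientations — or a
#' single self-closing circle (the structure when the IRs have been lost or
#' collapsed). Graphs with dangling segment ends are reported as
#' `incomplete`, anything else as `other`.
#'
#' Before classification, self-links in multi-segment graphs are dropped
#' (with a warning) and isolated segments shorter than `min_segment_len` are
#' pruned as assembler debris.
#'
#' @param graph An [assembly_graph()].
#' @param min_segment_len Isolated segments shorter than this are pruned
#'   before classification; default 50 bases.
#' @return A list of class `topology_call` with elements `klass` (one of
#'   `"quadripartite"`, `"circular"`, `"incomplete"`, `"other"`), `lsc_id`,
#'   `ssc_id`, `ir_id` (quadripartite), `circle_id` (circular), and `walk`
#'   (the oriented traversal used for isomer extraction).
#' @export
classify_graph <- function(graph, min_segment_len = 50) {
  segments <- graph$segments
  if (!nrow(segments)) stop("empty assembly graph")
  links <- canonicalize_links(graph$links)

  if (nrow(segments) > 1 && nrow(links)) {
    self <- links$from_id == links$to_id
    if (any(self)) {
      warning("dropping ", sum(self), " self-link(s) before classification")
      links <- links[!self, , drop = FALSE]
    }
  }

  lens <- segment_lengths(segments)
  deg <- table(factor(c(links$from_id, links$to_id), levels = segments$id))
  isolated_small <- deg[segments$id] == 0 & !is.na(lens) & lens < min_segment_len
  if (any(isolated_small) && nrow(segments) > 1) {
    segments <- segments[!isolated_small, , drop = FALSE]
    lens <- lens[!isolated_small]
  }

  call <- structure(
    list(klass = "other", lsc_id = NA_character_, ssc_id = NA_character_,
         ir_id = NA_character_, circle_id = NA_character_, walk = NULL),
    class = "topology_call"
  )

  n_seg <- nrow(segments)
  n_link <- nrow(links)

  if (n_seg == 3 && n_link == 4) {
    incidence <- table(factor(c(links$from_id, links$to_id), levels = segments$id))
    ir <- names(incidence)[incidence == 4]
    sc <- names(incidence)[incidence == 2]
    if (length(ir) == 1 && length(sc) == 2) {
      sc_len <- lens[match(sc, segments$id)]
      ord <- order(-sc_len, sc) # longer single copy is the LSC; ties by id
      lsc <- sc[ord[1]]
      ssc <- sc[ord[2]]
      walk <- find_quadripartite_walk(links, lsc, ssc, ir)
      if (!is.null(walk)) {
        call$klass <- "quadripartite"
        call$lsc_id <- lsc
        call$ssc_id <- ssc
        call$ir_id <- ir
        call$walk <- walk
        return(call)
      }
    }
  }

  if (n_seg == 1 && n_link == 1 &&
      links$from_id[1] == segments$id[1] && links$to_id[1] == segments$id[1] &&
      links$from_orient[1] == links$to_orient[1]) {
    call$klass <- "circular"
    call$circle_id <- segments$id[1]
    call$walk <- tibble::tibble(seg = segments$id[1], orient = links$from_orient[1],
                                overlap = links$overlap[1] %||% 0L)
    return(call)
  }

  ends <- covered_ends(segments, links)
  if (any(!ends$covered)) {
    call$klass <- "incomplete"
    return(call)
  }
  call
}

# Which physical segment ends are touched by at least one link.
covered_ends <- function(segments, links) {
  ends <- tidyr::expand_grid(id = segments$id, side = c("start", "end"))
  if (!nrow(links)) {
    ends$covered <- FALSE
    return(ends)
  }
  touched <- dplyr::bind_rows(
    tibble::tibble(id = links$from_id,
                   side = ifelse(links$from_orient == "+", "end", "start")),
    tibble::tibble(id = links$to_id,
                   side = ifelse(links$to_orient == "+", "start", "end"))
  )
  key <- paste(touched$id, touched$side)
  ends$covered <- paste(ends$id, ends$side) %in% key
  ends
}

#' @export
print.topology_call <- function(x, ...) {
  cat("<topology_call>", x$klass)
  if (x$klass == "quadripartite") {
    cat(sprintf(" (LSC=%s SSC=%s IR=%s)", x$lsc_id, x$ssc_id, x$ir_id))
  }
  if (x$klass == "circular") cat(sprintf(" (%s)", x$circle_id))
  cat("\n")
  invisible(x)
}

oriented_seq <- function(graph, seg, orient) {
  s <- graph$segments$seq[match(seg, graph$segments$id)]
  if (is.na(s)) stop("segment ", seg, " has no stored sequence")
  if (orient == "-") revcomp(s) else s
}

walk_sequence <- function(graph, walk) {
  parts <- character(nrow(walk))
  for (i in seq_len(nrow(walk))) {
    s <- oriented_seq(graph, walk$seg[i], walk$orient[i])
    # overlap bases of the link into step i are trimmed from the successor;
    # the wrap-around link trims the tail of the final step instead
    if (i > 1) {
      ov <- walk$overlap[i - 1]
      if (ov > 0) s <- substr(s, ov + 1, nchar(s))
    }
    if (i == nrow(walk)) {
      ov <- walk$overlap[i]
      if (ov > 0) s <- substr(s, 1, nchar(s) - ov)
    }
    parts[i] <- s
  }
  paste(parts, collapse = "")
}

#' Extract chloroplast isomer sequences from a classified graph
#'
#' A quadripartite chloroplast graph encodes two genome configurations that
#' coexist equimolarly in the plant (heteroplasmy), differing only in the
#' relative orientation of the single-copy regions across the inverted
#' repeat. Both are emitted: isomer A follows the walk
#' LSC-IR-SSC-revcomp(IR); isomer B is identical except that the SSC is
#' reverse-complemented. For a single-circle graph, the one circular
#' sequence is returned. Link overlap bases are trimmed once per traversed
#' link.
#'
#' @param graph An [assembly_graph()] whose segments carry sequences.
#' @param call A [classify_graph()] result with `klass` `"quadripartite"` or
#'   `"circular"`.
#' @return A named character vector: `isomer_A` and `isomer_B`, or a single
#'   `circular` element.
#' @export
extract_isomers <- function(graph, call) {
  if (!call$klass %in% c("quadripartite", "circular")) {
    stop("no walkable structure: graph classified as '", call$klass, "'")
  }
  if (call$klass == "circular") {
    s <- oriented_seq(graph, call$walk$seg[1], "+")
    ov <- call$walk$overlap[1]
    if (ov > 0) s <- substr(s, 1, nchar(s) - ov)
    return(c(circular = s))
  }
  walk_a <- call$walk
  walk_b <- walk_a
  walk_b$orient[3] <- flip_orient(walk_b$orient[3])
  c(isomer_A = walk_sequence(graph, walk_a),
    isomer_B = walk_sequence(graph, walk_b))
}

#' Label contigs as chloroplast by alignment to a chloroplast genome
#'
#' A contig is labeled `"chloroplast"` when more than 90% of its length is
#' covered by alignments to the chloroplast genome and the overall alignment
#' similarity exceeds 95% (both strict). Used to purge chloroplast-derived
#' contigs from mitochondrial assemblies.
#'
#' @param contigs Tibble with columns `id` and `length` (or `seq`).
#' @param paf PAF alignments of the contigs (query) against the chloroplast
#'   genome, as from [read_paf()].
#' @param min_coverage Coverage threshold, default 0.90.
#' @param min_similarity Similarity threshold, default 0.95.
#' @return A tibble with columns `id`, `coverage`, `similarity`, `label`
#'   (`"chloroplast"` or `"other"`).
#' @export
label_chloroplast_contigs <- function(contigs, paf, min_coverage = 0.90,
                                      min_similarity = 0.95) {
  if (!"length" %in% names(contigs)) {
    contigs <- dplyr::mutate(contigs, length = nchar(.data$seq))
  }
  unknown <- setdiff(unique(paf$qname), contigs$id)
  if (length(unknown)) {
    stop("alignment to unknown contig id(s): ", paste(unknown, collapse = ", "))
  }
  per <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    id <- contigs$id[i]
    len <- contigs$length[i]
    hits <- paf[paf$qname == id, , drop = FALSE]
    if (!nrow(hits)) {
      return(tibble::tibble(id = id, coverage = 0, similarity = 0))
    }
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = hits$qstart + 1L, end = hits$qend)
    )))
    tibble::tibble(
      id = id,
      coverage = covered / len,
      similarity = sum(hits$matches) / sum(hits$blocklen)
    )
  })
  dplyr::mutate(per, label = ifelse(
    .data$coverage > min_coverage & .data$similarity > min_similarity,
    "chloroplast", "other"
  ))
}
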