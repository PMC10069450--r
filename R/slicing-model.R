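## Duplex geometry and AGO4 slicing kernel.
##
## Coordinates are 1-based positions within a strand, counted from its 5'
## end. In a duplex the passenger pairs the guide antiparallel: passenger
## position p pairs guide position (guide_anchor - p), where
## guide_anchor = guide length - overhang_3g + 1. For the canonical DCL3
## 24/23 product guide_anchor = 23, so the passenger 5' nucleotide pairs
## guide position 22 and the untemplated passenger 3' base (position 23)
## hangs past the guide 5' end.

#' Guide positions flanking the Argonaute scissile bond
#'
#' Argonaute slicing cleaves the substrate phosphodiester bond between the
#' nucleotides paired to guide positions 10 and 11, measured from the guide
#' 5' end. This accessor keeps the rule in one place; both
#' [slice_passenger()] and [slice_target()] use it.
#'
#' @return Integer vector `c(10L, 11L)`.
#' @examples
#' slice_site_guide_positions()
#' @export
slice_site_guide_positions <- function() c(10L, 11L)

#' Construct an siRNA duplex with explicit end geometry
#'
#' Builds a guide/passenger duplex in one of the two DCL3 dicing geometries:
#' `"d24_23"` (24-nt guide, 23-nt passenger whose 3'-terminal untemplated
#' nucleotide overhangs the guide 5' end by 1 nt; guide 3' end overhangs by
#' 2 nt) or `"d24_24"` (two 24-mers with 2-nt 3' overhangs at both ends).
#' `"custom"` accepts explicit overhangs for non-canonical geometries.
#'
#' Watson-Crick complementarity (A:U, G:C; G:U wobble counts as a mismatch)
#' is enforced over the paired region. Overhanging nucleotides -- including
#' the untemplated passenger 3' base -- are never checked.
#'
#' @param guide,passenger RNA strings, 5'->3'.
#' @param geometry `"d24_23"`, `"d24_24"` or `"custom"`.
#' @param overhang_5g,overhang_3g For `geometry = "custom"`: nucleotides by
#'   which the passenger 3' end extends past the guide 5' end, and the guide
#'   3' end past the passenger 5' end.
#' @return An object of class `sirna_duplex`: a list with elements `guide`,
#'   `passenger`, `geometry`, `overhang_5g`, `overhang_3g`, `paired_len`,
#'   and `guide_anchor`.
#' @examples
#' g <- "AUGGCAUCGAUCGAUCGAUCGAUC"
#' p <- paste0(rna_revcomp(substr(g, 1, 22)), "G")
#' build_duplex(g, p, "d24_23")
#' @export
build_duplex <- function(guide, passenger,
                         geometry = c("d24_23", "d24_24", "custom"),
                         overhang_5g = NULL, overhang_3g = NULL) {
  geometry <- arg_match(geometry)
  check_rna(guide, "guide")
  check_rna(passenger, "passenger")
  gl <- nchar(guide)
  pl <- nchar(passenger)

  if (geometry == "d24_23") {
    if (gl != 24L || pl != 23L) {
      abort(sprintf(
        "geometry 'd24_23' requires a 24-nt guide and 23-nt passenger, got %d/%d",
        gl, pl))
    }
    overhang_5g <- 1L; overhang_3g <- 2L
  } else if (geometry == "d24_24") {
    if (gl != 24L || pl != 24L) {
      abort(sprintf(
        "geometry 'd24_24' requires two 24-nt strands, got %d/%d", gl, pl))
    }
    overhang_5g <- 2L; overhang_3g <- 2L
  } else {
    if (is.null(overhang_5g) || is.null(overhang_3g)) {
      abort("geometry 'custom' requires `overhang_5g` and `overhang_3g`")
    }
    overhang_5g <- as.integer(overhang_5g)
    overhang_3g <- as.integer(overhang_3g)
  }

  paired_len <- gl - overhang_3g
  if (paired_len != pl - overhang_5g || paired_len < 1L) {
    abort(sprintf(
      "inconsistent geometry: guide %d - overhang_3g %d != passenger %d - overhang_5g %d",
      gl, overhang_3g, pl, overhang_5g))
  }
  anchor <- gl - overhang_3g + 1L

  gc <- strand_chars(guide)
  pc <- strand_chars(passenger)
  pp <- seq_len(paired_len)
  bad <- which(!wc_pair(pc[pp], gc[anchor - pp]))
  if (length(bad) > 0) {
    p <- bad[1]
    abort(sprintf(
      "complementarity error: passenger position %d (%s) does not pair guide position %d (%s)",
      p, pc[p], anchor - p, gc[anchor - p]))
  }

  structure(
    list(guide = guide, passenger = passenger, geometry = geometry,
         overhang_5g = overhang_5g, overhang_3g = overhang_3g,
         paired_len = paired_len, guide_anchor = anchor),
    class = "sirna_duplex")
}

#' @export
print.sirna_duplex <- function(x, ...) {
  cat(sprintf("<sirna_duplex %s>\n", x$geometry))
  cat(sprintf("  guide     5'-%s-3' (%d nt)\n", x$guide, nchar(x$guide)))
  cat(sprintf("  passenger 5'-%s-3' (%d nt)\n", x$passenger, nchar(x$passenger)))
  cat(sprintf("  paired region %d nt; passenger 3' overhang past guide 5': %d nt; guide 3' overhang: %d nt\n",
              x$paired_len, x$overhang_5g, x$overhang_3g))
  invisible(x)
}

new_slice_result <- function(parent, cut_after, sliced) {
  if (sliced) {
    res <- list(
      cut_after_position = as.integer(cut_after),
      frag5 = substr(parent, 1L, cut_after),
      frag3 = substr(parent, cut_after + 1L, nchar(parent)),
      sliced = TRUE)
  } else {
    res <- list(cut_after_position = NA_integer_,
                frag5 = NA_character_, frag3 = NA_character_,
                sliced = FALSE)
  }
  structure(res, class = "slice_result")
}

#' @export
print.slice_result <- function(x, ...) {
  if (x$sliced) {
    cat(sprintf("<slice_result> cut after position %d: 5' %s (%d nt) | 3' %s (%d nt)\n",
                x$cut_after_position, x$frag5, nchar(x$frag5),
                x$frag3, nchar(x$frag3)))
  } else {
    cat("<slice_result> not sliced\n")
  }
  invisible(x)
}

#' Slice the passenger strand of an siRNA duplex
#'
#' Cuts the passenger between the two nucleotides paired to guide positions
#' 10 and 11 (see [slice_site_guide_positions()]). For the DCL3 24/23
#' geometry this yields a 12-nt 5' fragment and an 11-nt 3' fragment; a
#' 24-nt passenger of a 24/24 duplex yields two 12-nt fragments -- the 5'
#' product is 12 nt regardless of passenger length.
#'
#' @param duplex An [build_duplex()] object.
#' @return A `slice_result`: `cut_after_position` (1-based position in the
#'   passenger after which the bond was cut), `frag5`, `frag3`, `sliced`.
#'   If the paired region does not cover guide positions 10 and 11 the
#'   result has `sliced = FALSE`.
#' @examples
#' g <- "AUGGCAUCGAUCGAUCGAUCGAUC"
#' p <- paste0(rna_revcomp(substr(g, 1, 22)), "G")
#' slice_passenger(build_duplex(g, p, "d24_23"))
#' @export
slice_passenger <- function(duplex) {
  stopifnot(inherits(duplex, "sirna_duplex"))
  site <- slice_site_guide_positions()
  anchor <- duplex$guide_anchor
  ## guide positions covered by the paired region
  g_lo <- anchor - duplex$paired_len
  g_hi <- anchor - 1L
  if (site[1] < g_lo || site[2] > g_hi) {
    return(new_slice_result(duplex$passenger, NA, FALSE))
  }
  cut_after <- anchor - site[2]  # passenger partner of guide position 11
  pl <- nchar(duplex$passenger)
  if (cut_after < 1L || cut_after >= pl) {
    return(new_slice_result(duplex$passenger, NA, FALSE))
  }
  new_slice_result(duplex$passenger, cut_after, TRUE)
}

#' Align a guide to a target transcript
#'
#' Describes an antiparallel guide/target pairing: 1-based target position
#' `offset` pairs guide position 1, so guide position `i` pairs target
#' position `offset - (i - 1)`.
#'
#' @param guide,target RNA strings, 5'->3'.
#' @param offset 1-based target position paired with guide position 1.
#' @return An object of class `guide_target_alignment`.
#' @export
align_guide_target <- function(guide, target, offset) {
  check_rna(guide, "guide")
  check_rna(target, "target")
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L || offset > nchar(target)) {
    abort(sprintf("alignment error: offset %s outside target bounds [1, %d]",
                  offset, nchar(target)))
  }
  structure(list(guide = guide, target = target, offset = offset),
            class = "guide_target_alignment")
}

#' Slice a target RNA programmed by a guide
#'
#' Applies the Argonaute cleavage rule to a [align_guide_target()]
#' alignment: if every guide position in `require_match` (default 9-11,
#' since mismatches there abolish slicing) is Watson-Crick paired to its
#' target partner, the target is cut between the nucleotides opposite guide
#' positions 10 and 11. A fully complementary 23-nt target in the 24/23
#' register yields a 12-nt 5' fragment.
#'
#' @param aln A `guide_target_alignment`.
#' @param require_match Integer vector of guide positions that must be
#'   perfectly paired for cleavage; default `c(9, 10, 11)`.
#' @return A `slice_result` on the target strand; `sliced = FALSE` when a
#'   required position is mismatched or unpaired, or when the cut would not
#'   fall between two internal target nucleotides.
#' @examples
#' g <- "AUGGCAUCGAUCGAUCGAUCGAUC"
#' t23 <- rna_revcomp(substr(g, 1, 22))  # 22-nt complement...
#' t23 <- paste0(t23, "C")               # ...plus a 3' base past guide 5'
#' slice_target(align_guide_target(g, t23, offset = 22))
#' @export
slice_target <- function(aln, require_match = c(9L, 10L, 11L)) {
  stopifnot(inherits(aln, "guide_target_alignment"))
  site <- slice_site_guide_positions()
  tl <- nchar(aln$target)
  gc <- strand_chars(aln$guide)
  tc <- strand_chars(aln$target)
  partner <- function(i) aln$offset - (i - 1L)  # target position of guide i

  ## cut falls between the target partners of guide positions 10 and 11
  cut_after <- partner(site[2])
  if (cut_after < 1L || cut_after >= tl ||
      partner(site[1]) > tl || site[2] > nchar(aln$guide)) {
    return(new_slice_result(aln$target, NA, FALSE))
  }
  for (i in as.integer(require_match)) {
    t <- partner(i)
    ok <- i <= nchar(aln$guide) && t >= 1L && t <= tl && wc_pair(gc[i], tc[t])
    if (!ok) return(new_slice_result(aln$target, NA, FALSE))
  }
  new_slice_result(aln$target, cut_after, TRUE)
}

#' Is the guide seed region left single-stranded by a bound fragment?
#'
#' A retained passenger 5' fragment pairs the guide 3'-ward of the seed: a
#' 12-mer occupies guide positions 11-22 under the 24/23 register, leaving
#' seed positions 2-8 free to initiate target pairing. Returns `TRUE` iff
#' no nucleotide of `bound_fragment` pairs a guide position in 2-8.
#'
#' @param guide RNA string.
#' @param bound_fragment RNA string pairing the guide from its most-3'
#'   paired position (position `length(guide) - 1` under the canonical
#'   register); `""` or `NULL` means nothing is bound.
#' @return Logical scalar.
#' @export
seed_exposure <- function(guide, bound_fragment) {
  check_rna(guide, "guide")
  if (is.null(bound_fragment) || !nzchar(bound_fragment)) return(TRUE)
  check_rna(bound_fragment, "bound_fragment")
  anchor <- nchar(guide) - 1L  # guide 3' overhang of 2 nt
  np <- min(nchar(bound_fragment), anchor - 1L)
  paired_guide_pos <- anchor - seq_len(np)
  !any(paired_guide_pos %in% 2:8)
}
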