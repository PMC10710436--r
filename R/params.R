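#' Affine-gap penalty parameters
#'
#' An affine-gap penalty scheme charges `m` per matched base, `x` per
#' substituted base, and `o + n * e` for a gap of length `n` (so the first
#' gap base costs `o + e`). The relative sizes of `x`, `o` and `e` decide
#' which of the many equivalent representations of a complex variant an
#' aligner reports, which is why a fixed scheme doubles as a variant
#' representation standard.
#'
#' @param m Match penalty (non-negative).
#' @param x Substitution penalty (positive after normalization).
#' @param o Gap-opening penalty (non-negative).
#' @param e Gap-extension penalty (positive).
#' @return An object of class `affine_params`.
#' @examples
#' affine_params(0, 5, 6, 2) # the standard representation penalties
#' @export
affine_params <- function(m, x, o, e) {
  stopifnot(is.numeric(m), is.numeric(x), is.numeric(o), is.numeric(e))
  if (m < 0 || x < 0 || o < 0 || e <= 0) {
    stop("invalid affine parameters: require m >= 0, x >= 0, o >= 0, e > 0")
  }
  structure(list(m = as.numeric(m), x = as.numeric(x),
                 o = as.numeric(o), e = as.numeric(e)),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("affine penalties (m, x, o, e) = (%g, %g, %g, %g)\n",
              x$m, x$x, x$o, x$e))
  invisible(x)
}

#' @export
format.affine_params <- function(x, ...) {
  sprintf("(%g, %g, %g, %g)", x$m, x$x, x$o, x$e)
}

as_affine_params <- function(p) {
  if (inherits(p, "affine_params")) return(p)
  if (is.character(p) && length(p) == 1) return(preset_params(p))
  if (is.numeric(p) && length(p) == 4) return(affine_params(p[1], p[2], p[3], p[4]))
  stop("cannot interpret affine parameters; give an affine_params object, ",
       "a preset name, or a numeric vector (m, x, o, e)")
}

#' Normalize affine-gap parameters to m = 0, x = 1
#'
#' Two penalty schemes are equivalent when they rank all global alignments of
#' any sequence pair identically. Every alignment of sequences with total
#' length `L` satisfies `2 * matches + 2 * subs + gap_bases = L_a + L_b`, so
#' shifting half the match penalty onto every consumed base leaves the
#' ranking unchanged: `x <- x + m`, `o` unchanged as an event cost but each
#' gap base absorbs `m / 2` (`e <- e + m / 2`, `o <- o + m / 2` so the first
#' gap base also pays its share), after which `m = 0`. Dividing by the new
#' `x` rescales to `x = 1`.
#'
#' @param p An [affine_params] object (or numeric length-4 vector).
#' @return A normalized `affine_params` with `m = 0`, `x = 1`.
#' @examples
#' normalize_params(affine_params(0, 5, 6, 2))   # (0, 1, 1.2, 0.4)
#' normalize_params(affine_params(2, 4, 4, 2))   # (0, 1, 0.833, 0.5)
#' @export
normalize_params <- function(p) {
  p <- as_affine_params(p)
  x2 <- p$x + p$m
  if (x2 <= 0) stop("cannot normalize: x + m must be positive")
  o2 <- p$o + p$m / 2
  e2 <- p$e + p$m / 2
  affine_params(0, 1, o2 / x2, e2 / x2)
}

#' Does a penalty scheme decompose substitutions into gaps?
#'
#' For normalized parameters, a substitution is never reported when
#' `2 * (o + e) < x`: a one-base insertion plus a one-base deletion is then
#' always cheaper than substituting the base. Schemes in this regime model
#' copy-number-style alignment in repetitive sequence.
#'
#' @param p Normalized [affine_params].
#' @return `TRUE` if substitutions always decompose into a 1-bp insertion
#'   plus a 1-bp deletion; at equality the substitution is kept.
#' @export
snp_decomposes <- function(p) {
  p <- as_affine_params(p)
  2 * (p$o + p$e) < p$x
}

#' Double affine-gap parameters
#'
#' Double affine alignment keeps two gap cost lines `g1(n) = o1 + n * e1` and
#' `g2(n) = o2 + n * e2` and charges the cheaper one; conventionally
#' `o2 > o1` and `e2 < e1`, so `g1` governs short gaps and `g2` long ones.
#'
#' @param first,second [affine_params] holding the two (o, e) pairs.
#' @return An object of class `double_affine_params`.
#' @export
double_affine_params <- function(first, second) {
  first <- as_affine_params(first)
  second <- as_affine_params(second)
  if (!(second$o >= first$o && second$e < first$e)) {
    stop("double affine parameters require o2 >= o1 and e2 < e1")
  }
  structure(list(first = first, second = second),
            class = "double_affine_params")
}

#' Crossover gap length of a double affine scheme
#'
#' The two gap cost lines intersect at `n = (o2 - o1) / (e1 - e2)`; below
#' this length `g1` is cheaper, above it `g2` is.
#'
#' @param d A [double_affine_params] object.
#' @return The real-valued crossover gap length.
#' @export
double_affine_crossover <- function(d) {
  stopifnot(inherits(d, "double_affine_params"))
  e1 <- d$first$e; e2 <- d$second$e
  if (e1 == e2) stop("crossover undefined when e1 == e2")
  (d$second$o - d$first$o) / (e1 - e2)
}

#' Named design-point presets
#'
#' Four normalized-integer design points span the affine-gap design space:
#'
#' * `B = (0, 3, 2, 1)`: globally minimizes `2 * DE + ED` (distinct edits
#'   weighted twice as heavily as edit distance); used for the distance
#'   metrics.
#' * `C = (0, 5, 6, 2)`: the proposed representation standard, the
#'   approximate centroid of common short- and long-read aligner penalties;
#'   normalized `(0, 1, 1.2, 0.4)`.
#' * `A = (0, 8, 1, 1)`: a copy-number-aligner-like point with
#'   `2 * (o + e) < x`, so every substitution decomposes into a 1-bp
#'   insertion plus a 1-bp deletion. The exact integers are a package
#'   choice within that regime.
#' * `D = (0, 2, 4, 1)`: an assembly-aligner-like point with gap penalties
#'   high relative to substitutions; likewise a package choice.
#'
#' `"edlib"` (alias `"fragmented"`) gives unit costs `(0, 1, 0, 1)`, the
#' pure edit-distance point that yields maximally fragmented
#' representations.
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`, `"edlib"`, `"fragmented"`.
#' @return An [affine_params] object.
#' @examples
#' preset_params("C")
#' @export
preset_params <- function(name) {
  switch(toupper(as.character(name)[1]),
    "A" = affine_params(0, 8, 1, 1),
    "B" = affine_params(0, 3, 2, 1),
    "C" = affine_params(0, 5, 6, 2),
    "D" = affine_params(0, 2, 4, 1),
    "EDLIB" = ,
    "FRAGMENTED" = affine_params(0, 1, 0, 1),
    stop("unknown preset: ", name)
  )
}
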