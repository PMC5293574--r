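#' Conformation helpers
#'
#' A conformation is a plain (N+1) x 3 numeric matrix of bead positions
#' (columns x, y, z), lengths in units of \eqn{l_{max}}. The wall is the
#' plane z = 0, so a bead's surface distance is its z coordinate.
#'
#' @param conf an (N+1) x 3 position matrix.
#' @return \code{bond_vectors()}: an N x 3 matrix of bond vectors;
#'   \code{bond_lengths()}: a length-N numeric vector;
#'   \code{bond_angles()}: the N - 1 interior angles \eqn{\theta} in
#'   radians (straight = \eqn{\pi}).
#' @name conformation
NULL

#' @rdname conformation
#' @export
bond_vectors <- function(conf) {
  diff(conf)
}

#' @rdname conformation
#' @export
bond_lengths <- function(conf) {
  sqrt(rowSums(bond_vectors(conf)^2))
}

#' @rdname conformation
#' @export
bond_angles <- function(conf) {
  b <- bond_vectors(conf)
  u <- b / sqrt(rowSums(b^2))
  n <- nrow(u)
  if (n < 2) return(numeric(0))
  cphi <- rowSums(u[-n, , drop = FALSE] * u[-1, , drop = FALSE])
  cphi <- pmin(1, pmax(-1, cphi))
  # interior angle theta = pi - phi, so cos(theta) = -cos(phi)
  acos(-cphi)
}

#' Check conformation invariants
#'
#' Verifies that every bond length lies strictly inside the FENE range and
#' that no bead is below the wall (z >= 0).
#'
#' @param conf an (N+1) x 3 position matrix.
#' @param params a [model_params()] object.
#' @param strict if TRUE (default) violations raise an error; otherwise a
#'   logical is returned.
#' @return TRUE invisibly (strict) or a logical flag.
#' @export
check_conformation <- function(conf, params, strict = TRUE) {
  ok <- is.matrix(conf) && ncol(conf) == 3 && nrow(conf) == params$n_bonds + 1
  msg <- NULL
  if (!ok) {
    msg <- sprintf("expected a %d x 3 position matrix", params$n_bonds + 1)
  } else {
    bl <- bond_lengths(conf)
    if (any(bl <= params$l_min) || any(bl >= params$l_max)) {
      ok <- FALSE
      msg <- sprintf("bond length outside FENE range (%g, %g): [%g, %g]",
                     params$l_min, params$l_max, min(bl), max(bl))
    } else if (any(conf[, 3] < 0)) {
      ok <- FALSE
      msg <- sprintf("bead below wall: min z = %g", min(conf[, 3]))
    }
  }
  if (strict) {
    if (!ok) stop(msg, call. = FALSE)
    return(invisible(TRUE))
  }
  ok
}
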