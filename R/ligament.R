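# Tension-only nonlinear spring model of the collateral ligaments
# (Blankevoort force-strain law). Each bundle stores its attachment points
# at the reference (full-extension) pose, the stiffness k (N; the law is
# expressed in dimensionless strain so k carries force units), the
# reference strain eps_r, and the linear-limit strain eps_l. The quadratic
# toe region spans 0 <= eps <= 2*eps_l and transitions continuously to the
# linear region f = k*(eps - eps_l) at eps = 2*eps_l.

# direction tags -> model-frame unit vectors (+x medial, +y anterior,
# +z proximal)
.shift_directions <- list(
  anterior = c(0, 1, 0), posterior = c(0, -1, 0),
  medial = c(1, 0, 0), lateral = c(-1, 0, 0),
  proximal = c(0, 0, 1), distal = c(0, 0, -1))

#' Zero-load length from reference length and reference strain
#'
#' The length at which the ligament first becomes taut:
#' `L0 = Lr / (1 + eps_r)`. A negative reference strain (slack at full
#' extension) gives `L0 > Lr`.
#'
#' @param L_r reference length (mm), > 0.
#' @param eps_r reference strain (dimensionless), > -1.
#' @return zero-load length (mm).
#' @export
#' @examples
#' zero_load_length(60, 0.04)   # 57.6923
#' zero_load_length(57, -0.05)  # 60
zero_load_length <- function(L_r, eps_r) {
  assert_scalar_num(L_r, "L_r", 0, strict_lower = TRUE)
  if (!is.numeric(eps_r) || length(eps_r) != 1L || eps_r <= -1)
    stop_tkr("`eps_r` must be > -1 (got %s)", format(eps_r))
  L_r / (eps_r + 1)
}

#' Ligament bundle
#'
#' @param name bundle label, conventionally `"MCL"` or `"LCL"`.
#' @param origin femoral attachment point (mm, model frame).
#' @param insertion tibial/fibular attachment point (mm).
#' @param k stiffness parameter (N).
#' @param eps_r reference strain at the full-extension pose.
#' @param eps_l linear-limit strain; the force law is quadratic on
#'   `[0, 2*eps_l]` and linear beyond.
#' @param n_strands number of parallel spring elements the bundle is split
#'   into for solver export; the total bundle force is independent of
#'   `n_strands` (`k` is divided equally).
#' @return object of class `ligament_bundle` with derived `L_r`
#'   (`||insertion - origin||`) and `L_0` (via [zero_load_length()]).
#' @export
ligament_bundle <- function(name, origin, insertion, k, eps_r,
                            eps_l = 0.03, n_strands = 1L) {
  assert_scalar_num(k, "k", 0, strict_lower = TRUE)
  assert_scalar_num(eps_l, "eps_l", 0, strict_lower = TRUE)
  if (n_strands < 1L) stop_tkr("`n_strands` must be >= 1")
  origin <- as.numeric(origin); insertion <- as.numeric(insertion)
  if (length(origin) != 3L || length(insertion) != 3L)
    stop_tkr("attachment points must be 3-vectors")
  L_r <- sqrt(sum((insertion - origin)^2))
  if (L_r <= 1e-12)
    stop_tkr("ligament '%s': origin and insertion coincide (L_r = 0)", name)
  L_0 <- zero_load_length(L_r, eps_r)
  structure(list(name = name, origin = origin, insertion = insertion,
                 k = k, eps_r = eps_r, eps_l = eps_l, L_r = L_r, L_0 = L_0,
                 n_strands = as.integer(n_strands)),
            class = "ligament_bundle")
}

#' @export
print.ligament_bundle <- function(x, ...) {
  cat(sprintf(
    "ligament_bundle %s: k = %g N, eps_r = %g, eps_l = %g, L_r = %.4f mm, L_0 = %.4f mm\n",
    x$name, x$k, x$eps_r, x$eps_l, x$L_r, x$L_0))
  invisible(x)
}

#' Tension-only ligament force at a given strain
#'
#' Piecewise force-strain law: zero in compression, quadratic toe region
#' `f = k*eps^2 / (4*eps_l)` for `0 <= eps <= 2*eps_l`, linear
#' `f = k*(eps - eps_l)` beyond. Both branches equal `k*eps_l` at
#' `eps = 2*eps_l`, so the law is continuous and non-decreasing.
#'
#' @param eps strain (dimensionless), vectorized.
#' @param k stiffness (N).
#' @param eps_l linear-limit strain.
#' @return axial force (N).
#' @export
ligament_force_strain <- function(eps, k, eps_l) {
  f <- numeric(length(eps))
  toe <- eps >= 0 & eps <= 2 * eps_l
  lin <- eps > 2 * eps_l
  f[toe] <- 0.25 * k * eps[toe]^2 / eps_l
  f[lin] <- k * (eps[lin] - eps_l)
  f
}

#' Bundle force at a given current length
#'
#' Computes strain `eps = (L - L_0)/L_0` and evaluates the force law. The
#' result is the bundle total (strand subdivision cancels).
#'
#' @param L current length (mm), vectorized.
#' @param bundle a [ligament_bundle()].
#' @return axial force (N).
#' @export
ligament_force <- function(L, bundle) {
  if (any(L <= 0)) stop_tkr("ligament length must be positive")
  eps <- (L - bundle$L_0) / bundle$L_0
  ligament_force_strain(eps, bundle$k, bundle$eps_l)
}

#' Default MCL and LCL bundles
#'
#' Standard collateral-ligament parameters: MCL k = 8250 N with reference
#' strain 0.04 (taut at full extension); LCL k = 6000 N with reference
#' strain -0.05 (slack at full extension). Reference lengths are measured
#' from the supplied attachment landmarks.
#'
#' @param landmarks landmark list as from [synthetic_landmarks()]:
#'   `femur$mcl_origin`, `femur$lcl_origin`, `tibia$mcl_insertion`,
#'   `fibula$lcl_insertion`.
#' @param eps_l linear-limit strain for both bundles.
#' @return list with elements `MCL` and `LCL`.
#' @export
make_default_bundles <- function(landmarks = synthetic_landmarks(),
                                 eps_l = 0.03) {
  list(
    MCL = ligament_bundle("MCL", landmarks$femur$mcl_origin,
                          landmarks$tibia$mcl_insertion,
                          k = 8250, eps_r = 0.04, eps_l = eps_l),
    LCL = ligament_bundle("LCL", landmarks$femur$lcl_origin,
                          landmarks$fibula$lcl_insertion,
                          k = 6000, eps_r = -0.05, eps_l = eps_l)
  )
}

#' Shift both attachment points of a bundle by the same vector
#'
#' Translating origin and insertion together preserves the difference
#' vector, hence the reference length `L_r` and zero-load length `L_0` —
#' the geometry moves, the pre-tension does not.
#'
#' @param b a [ligament_bundle()].
#' @param direction one of `"anterior"`, `"posterior"`, `"medial"`,
#'   `"lateral"`, `"proximal"`, `"distal"`.
#' @param distance shift distance (mm), >= 0.
#' @return the shifted bundle.
#' @export
perturb_attachments <- function(b, direction, distance) {
  if (!direction %in% names(.shift_directions))
    stop_tkr("unknown shift direction '%s'", direction)
  assert_scalar_num(distance, "distance", 0)
  v <- .shift_directions[[direction]] * distance
  b$origin <- b$origin + v
  b$insertion <- b$insertion + v
  b
}

#' Scale a ligament parameter by a signed percentage
#'
#' Multiplicative perturbation `value * (1 + pct/100)`. When `eps_r` is
#' scaled, the zero-load length is recomputed from the unchanged reference
#' length (the pre-tension changes, the geometry does not).
#'
#' @param b a [ligament_bundle()].
#' @param which `"eps_r"` or `"k"`.
#' @param pct signed percentage, > -100.
#' @return the perturbed bundle.
#' @export
scale_parameter <- function(b, which = c("eps_r", "k"), pct) {
  which <- match.arg(which)
  if (!is.numeric(pct) || length(pct) != 1L || pct <= -100)
    stop_tkr("`pct` must be a percentage > -100")
  fac <- 1 + pct / 100
  if (which == "k") {
    b$k <- b$k * fac
  } else {
    new_eps <- b$eps_r * fac
    if (new_eps <= -1)
      stop_tkr("scaled eps_r = %g is <= -1", new_eps)
    b$eps_r <- new_eps
    b$L_0 <- zero_load_length(b$L_r, new_eps)
  }
  b
}

#' Serialize ligament bundles to a YAML block
#' @param bundles list of [ligament_bundle()] objects.
#' @param path optional file path; if omitted the YAML text is returned.
#' @return YAML string (invisibly when written to file).
#' @export
ligaments_to_yaml <- function(bundles, path = NULL) {
  lst <- lapply(bundles, function(b)
    list(name = b$name, origin = as.numeric(b$origin),
         insertion = as.numeric(b$insertion), k = b$k, eps_r = b$eps_r,
         eps_l = b$eps_l, n_strands = b$n_strands))
  txt <- yaml::as.yaml(list(ligaments = unname(lst)))
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Read ligament bundles from YAML
#' @param path file path (or YAML text via `text =`).
#' @param text YAML string, used when `path` is `NULL`.
#' @return named list of [ligament_bundle()] objects.
#' @export
ligaments_from_yaml <- function(path = NULL, text = NULL) {
  doc <- if (!is.null(path)) yaml::read_yaml(path) else
    yaml::yaml.load(text)
  out <- lapply(doc$ligaments, function(d)
    ligament_bundle(d$name, d$origin, d$insertion, d$k, d$eps_r,
                    eps_l = d$eps_l %||% 0.03,
                    n_strands = d$n_strands %||% 1L))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
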