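#' Uniaxial loading program
#'
#' An ordered sequence of stretch targets walked from the reference state
#' \eqn{\Lambda = 1}. A monotonic program has a single target (elongation to
#' rupture); a cyclic program alternates loading and unloading segments
#' (quasi-static cyclic tension), e.g. `c(3, 1, 6, 1, 9)` for cycles of
#' growing amplitude. Quasi-static: programs are pure stretch paths, no rate
#' variable.
#'
#' @param targets numeric vector of successive stretch targets, all >= 1.
#' @param points_per_segment samples per segment (>= 2), recycled.
#' @param kind `"monotonic"` or `"cyclic"`; inferred from the path shape if
#'   missing.
#' @param label free-text label.
#' @param cation free-text cation tag (e.g. `"Ca+2"`, `"Fe+3"`).
#' @return an object of class `"loading_program"`.
#' @examples
#' loading_program(9)                      # monotonic to rupture stretch 9
#' loading_program(c(3, 1, 6, 1, 9))       # growing-amplitude cycles
#' @export
loading_program <- function(targets, points_per_segment = 25L,
                            kind = NULL, label = "", cation = "") {
  if (!is.numeric(targets) || length(targets) < 1L || any(targets < 1)) {
    stop("`targets` must be numeric stretch targets >= 1")
  }
  npts <- as.integer(rep_len(points_per_segment, length(targets)))
  if (any(npts < 2L)) stop("each segment needs at least 2 sample points")
  path <- c(1, targets)
  dirs <- sign(diff(path))
  trivial <- length(targets) == 1L && targets[1] == 1  # hold at the reference state
  if (!trivial && any(dirs == 0)) {
    stop("consecutive equal stretch targets give an empty segment")
  }
  inferred <- if (length(targets) == 1L && dirs[1] >= 0) "monotonic" else "cyclic"
  if (is.null(kind)) kind <- inferred
  kind <- match.arg(kind, c("monotonic", "cyclic"))
  if (kind == "cyclic" && length(dirs) > 1L && any(diff(dirs) == 0)) {
    stop("cyclic programs must alternate loading and unloading segments")
  }
  if (kind == "monotonic" && (length(targets) != 1L || dirs[1] < 0)) {
    stop("a monotonic program has a single non-decreasing target")
  }
  structure(
    list(targets = as.numeric(targets), points_per_segment = npts,
         kind = kind, label = label, cation = cation),
    class = "loading_program"
  )
}

#' @export
print.loading_program <- function(x, ...) {
  cat(sprintf("<loading_program: %s> 1 -> %s (%d samples)%s%s\n",
              x$kind, paste(format(x$targets), collapse = " -> "),
              nrow(program_path(x)),
              if (nzchar(x$label)) paste0(" label=", x$label) else "",
              if (nzchar(x$cation)) paste0(" cation=", x$cation) else ""))
  invisible(x)
}

#' Sampled stretch path of a loading program
#'
#' @param program a `"loading_program"`.
#' @return data frame with columns `stretch`, `branch` (`"load"`/`"unload"`),
#'   `cycle` (1-based loading-segment counter), starting at the reference
#'   state.
#' @export
program_path <- function(program) {
  stopifnot(inherits(program, "loading_program"))
  from <- 1
  stretch <- 1
  branch <- "load"
  cyc <- integer(0)
  cycle <- 1L
  cyc <- 1L
  for (i in seq_along(program$targets)) {
    to <- program$targets[i]
    seg <- seq(from, to, length.out = program$points_per_segment[i] + 1L)[-1L]
    dir <- if (to >= from) "load" else "unload"
    if (i > 1L && dir == "load") cycle <- cycle + 1L
    stretch <- c(stretch, seg)
    branch <- c(branch, rep(dir, length(seg)))
    cyc <- c(cyc, rep(cycle, length(seg)))
    from <- to
  }
  data.frame(stretch = stretch, branch = branch, cycle = cyc)
}

#' Stress-stretch curve container
#'
#' A data frame of ordered (stretch, nominal stress) samples with the
#' loading-program metadata attached.
#'
#' @param stretch,stress equal-length numeric vectors; stretch >= 1.
#' @param branch,cycle optional per-sample branch labels and cycle indices.
#' @param program the generating `"loading_program"`, if any.
#' @param stress_unit declared stress unit.
#' @param label,cation metadata tags.
#' @return object of class `c("stress_stretch_curve", "data.frame")`.
#' @export
stress_stretch_curve <- function(stretch, stress, branch = NULL, cycle = NULL,
                                 program = NULL, stress_unit = "kPa",
                                 label = "", cation = "") {
  if (length(stretch) != length(stress)) {
    stop("`stretch` and `stress` must have equal length")
  }
  if (any(stretch < 1)) {
    stop(sprintf("tension-only curves require stretch >= 1 (violated at row %d)",
                 which(stretch < 1)[1]))
  }
  df <- data.frame(stretch = as.numeric(stretch), stress = as.numeric(stress))
  if (!is.null(branch)) df$branch <- as.character(branch)
  if (!is.null(cycle)) df$cycle <- as.integer(cycle)
  structure(df, program = program, stress_unit = stress_unit,
            label = label, cation = cation,
            class = c("stress_stretch_curve", "data.frame"))
}

#' @export
print.stress_stretch_curve <- function(x, ...) {
  cat(sprintf("Stress-stretch curve: %d samples, stretch [%.3g, %.3g], stress in %s\n",
              nrow(x), min(x$stretch), max(x$stretch),
              attr(x, "stress_unit") %||% "?"))
  if (nzchar(attr(x, "label") %||% "")) cat("  label:", attr(x, "label"), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward-simulate a stress-stretch curve
#'
#' Walks the loading program in order, accumulating the damage state (the
#' running maximum chain stretch) and evaluating the nominal stress at each
#' sample. The first-loading branch of a cyclic program coincides pointwise
#' with a monotonic simulation through the same stretches.
#'
#' @param params a `"dnh_params"` object.
#' @param program a `"loading_program"`.
#' @param control a `"dnh_control"` object.
#' @return a `"stress_stretch_curve"`.
#' @examples
#' curve <- dnh_simulate(dnh_default_params(), loading_program(c(3, 1, 6)))
#' @export
dnh_simulate <- function(params, program, control = dnh_control()) {
  stopifnot(inherits(params, "dnh_params"), inherits(program, "loading_program"))
  path <- program_path(program)
  dmg <- damage_state(1)
  stress <- numeric(nrow(path))
  for (i in seq_len(nrow(path))) {
    state <- uniaxial_kinematics(path$stretch[i], control$chain_stretch)
    dmg <- update_damage(dmg, state)
    stress[i] <- nominal_stress(path$stretch[i], dmg, params, control)
  }
  stress_stretch_curve(path$stretch, stress, branch = path$branch,
                       cycle = path$cycle, program = program,
                       stress_unit = params$stress_unit,
                       label = program$label, cation = program$cation)
}

#' Generate a synthetic (noisy) stress-stretch curve
#'
#' [dnh_simulate()] plus i.i.d. Gaussian measurement noise on the stress,
#' reproducible under the seed. `noise_sd = 0` returns the exact model
#' curve. This stands in for experimental tensile data: it emulates the J-
#' then S-shaped virgin hardening and the softened reloading loops of
#' alginate/polyacrylamide gels, but not instrument drift, specimen-to-
#' specimen variability, or rupture scatter.
#'
#' @param params,program,control as in [dnh_simulate()].
#' @param noise_sd standard deviation of the stress noise (stress units,
#'   >= 0).
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return a `"stress_stretch_curve"`.
#' @export
dnh_synthesize <- function(params, program, noise_sd = 0, seed = NULL,
                           control = dnh_control()) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  curve <- dnh_simulate(params, program, control)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a `seed` is required for noisy synthesis")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    curve$stress <- curve$stress + stats::rnorm(nrow(curve), sd = noise_sd)
  }
  curve
}

#' Small-strain elastic modulus from a tensile curve
#'
#' Least-squares slope of nominal stress against engineering strain
#' \eqn{\Lambda - 1} through the origin, on the virgin-path small-strain
#' window \eqn{\Lambda \le 1 +} `window`. Used as the frozen default for the
#' enthalpic modulus `E`, which the model takes from experiment rather than
#' fitting.
#'
#' @param curve a `"stress_stretch_curve"` (or data frame with `stretch`,
#'   `stress`).
#' @param window strain window half-width (default 0.05).
#' @return modulus in the curve's stress units.
#' @export
estimate_modulus <- function(curve, window = 0.05) {
  df <- as.data.frame(curve)
  if (!is.null(df$branch) && !is.null(df$cycle)) {
    df <- df[df$cycle == min(df$cycle) & df$branch == "load", , drop = FALSE]
  }
  df <- df[df$stretch <= 1 + window, , drop = FALSE]
  e <- df$stretch - 1
  use <- e > 0
  if (sum(use) < 2L) {
    stop(sprintf(
      "insufficient small-strain samples: %d virgin-path points with 1 < stretch <= %.4g (need >= 2)",
      sum(use), 1 + window
    ))
  }
  sum(e[use] * df$stress[use]) / sum(e[use]^2)
}
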