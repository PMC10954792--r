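# Synthetic agent-position clouds with analytically known spatial
# properties, for exercising the spatial metrics independently of the
# simulator.

#' Generate a synthetic agent cloud
#'
#' Deterministic (seeded) snapshot tables with known geometry:
#' \describe{
#'   \item{`hull_square`}{Four tumor cells at the corners of a 10 x 10
#'     square in the middle z-slice (hull area exactly 100 site^2), two
#'     active CTLs inside the hull, one active CTL outside it and one
#'     exhausted CTL inside. The expected [hull_ctl_density()] is
#'     2/100 = 0.02.}
#'   \item{`uniform`}{A tumor cell on every lattice site: the radial
#'     profile about the lattice center is flat up to shell discreteness,
#'     and the infiltrate percentage is 0.}
#'   \item{`shell`}{Tumor cells on every site whose distance from the
#'     center falls in one thin shell: all radial mass in one bin.}
#'   \item{`mixed`}{A random tumor ball of `n` cells with `n %/% 4` CTLs
#'     scattered among the remaining sites (seeded), for normalization
#'     and invariance checks.}
#' }
#'
#' @param kind one of `"hull_square"`, `"uniform"`, `"shell"`, `"mixed"`.
#' @param dims lattice dimensions (default `c(21, 21, 21)`).
#' @param n agent count for `"mixed"` (default 60).
#' @param seed RNG seed used by `"mixed"`.
#' @return agent table in the [snapshot_agents()] format.
#' @export
synthetic_agent_cloud <- function(kind = c("hull_square", "uniform", "shell",
                                           "mixed"),
                                  dims = c(21L, 21L, 21L), n = 60L, seed = 1L) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  lat <- make_lattice(dims)
  ctr <- (dims + 1) / 2
  zmid <- as.integer(round(ctr[3]))
  row <- function(type, x, y, z, state = "active") {
    data.frame(type = type, x = x, y = y, z = z,
               antigenicity = ifelse(type == "tumor", "HA", NA_character_),
               mutation = ifelse(type == "tumor", "WT", NA_character_),
               state = ifelse(type == "tumor", "alive", state),
               stringsAsFactors = FALSE)
  }
  out <- switch(kind,
    hull_square = {
      x0 <- as.integer(ctr[1]) - 5L
      sq <- rbind(c(x0, x0), c(x0 + 10L, x0), c(x0 + 10L, x0 + 10L),
                  c(x0, x0 + 10L))
      rbind(
        row("tumor", sq[, 1], sq[, 2], zmid),
        row("ctl", x0 + 3L, x0 + 4L, zmid),
        row("ctl", x0 + 7L, x0 + 6L, zmid),
        row("ctl", x0 + 15L, x0 + 2L, zmid),                  # outside hull
        row("ctl", x0 + 5L, x0 + 5L, zmid, state = "exhausted")
      )
    },
    uniform = row("tumor", lat$x, lat$y, lat$z),
    shell = {
      d <- sqrt((lat$x - ctr[1])^2 + (lat$y - ctr[2])^2 + (lat$z - ctr[3])^2)
      r0 <- min(dims) / 3
      keep <- which(d >= r0 & d < r0 + 1)
      row("tumor", lat$x[keep], lat$y[keep], lat$z[keep])
    },
    mixed = {
      set.seed(seed)
      d <- sqrt((lat$x - ctr[1])^2 + (lat$y - ctr[2])^2 + (lat$z - ctr[3])^2)
      ball <- order(d)[seq_len(n)]
      rest <- setdiff(seq_len(lat$nsite), ball)
      ctl <- sample(rest, max(1L, n %/% 4L))
      rbind(row("tumor", lat$x[ball], lat$y[ball], lat$z[ball]),
            row("ctl", lat$x[ctl], lat$y[ctl], lat$z[ctl]))
    })
  out$id <- seq_len(nrow(out))
  out[, c("id", "type", "x", "y", "z", "antigenicity", "mutation", "state")]
}
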