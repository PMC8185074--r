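## Ramachandran surrogate: smooth analytic basin mixtures per residue
## class instead of empirical statistical tables. Only the properties that
## matter downstream are encoded: L residues favor the alpha-R/beta
## regions, D residues are exact mirrors, and glycine is symmetric under
## (phi, psi) -> (-phi, -psi). Score = -log(unnormalized mixture density);
## lower is more favorable.

## basins: phi0, psi0, sd_phi, sd_psi, weight
.rama_basins <- list(
  general = data.frame(
    phi0 = c(-63, -120, 57),
    psi0 = c(-43, 135, 40),
    sd_phi = c(22, 28, 18),
    sd_psi = c(22, 32, 18),
    w = c(0.42, 0.45, 0.13)
  ),
  ## glycine: mirror-symmetrized pair set
  gly = data.frame(
    phi0 = c(-80, 80, -63, 63),
    psi0 = c(170, -170, -41, 41),
    sd_phi = c(30, 30, 25, 25),
    sd_psi = c(30, 30, 25, 25),
    w = c(0.25, 0.25, 0.25, 0.25)
  ),
  ## proline: phi restricted near -63
  pro = data.frame(
    phi0 = c(-63, -63),
    psi0 = c(-35, 148),
    sd_phi = c(12, 12),
    sd_psi = c(22, 25),
    w = c(0.5, 0.5)
  )
)

rama_class <- function(template) {
  code <- if (is.character(template)) template else template$code
  tpl <- get_template(code)
  if (tpl$base_code == "GLY") return(list(class = "gly", mirror = FALSE))
  cls <- if (tpl$base_code == "PRO") "pro" else "general"
  list(class = cls, mirror = identical(tpl$chirality, "D"))
}

rama_density <- function(basins, phi, psi) {
  dens <- 0
  for (k in seq_len(nrow(basins))) {
    dphi <- wrap_angle(phi - basins$phi0[k])
    dpsi <- wrap_angle(psi - basins$psi0[k])
    dens <- dens + basins$w[k] *
      exp(-0.5 * (dphi / basins$sd_phi[k])^2 -
           0.5 * (dpsi / basins$sd_psi[k])^2)
  }
  dens
}

#' Backbone torsion preference score
#'
#' Unitless score, lower is more favorable. D templates are scored via
#' the mirrored point (-phi, -psi) of their L parent's surface; the
#' glycine surface is itself mirror-symmetric.
#'
#' @param template a template code (e.g. "ALA", "DAL", "GLY") or template
#' @param phi,psi backbone torsions in degrees
#' @return numeric score (vectorized over phi/psi)
#' @export
rama_score <- function(template, phi, psi) {
  rc <- rama_class(template)
  if (rc$mirror) { phi <- -phi; psi <- -psi }
  dens <- rama_density(.rama_basins[[rc$class]], phi, psi)
  -log(dens + 1e-9)
}

#' Sample backbone torsions from the preference surface
#'
#' Draws (phi, psi) from the basin mixture of the template's class
#' (mirrored for D templates). Used for torsion seeding during macrocycle
#' closure.
#'
#' @param template template code or template object
#' @param n number of samples
#' @return data.frame with columns phi, psi (degrees)
#' @export
rama_sample <- function(template, n = 1) {
  rc <- rama_class(template)
  basins <- .rama_basins[[rc$class]]
  k <- sample.int(nrow(basins), n, replace = TRUE, prob = basins$w)
  phi <- wrap_angle(rnorm(n, basins$phi0[k], basins$sd_phi[k]))
  psi <- wrap_angle(rnorm(n, basins$psi0[k], basins$sd_psi[k]))
  if (rc$mirror) { phi <- wrap_angle(-phi); psi <- wrap_angle(-psi) }
  data.frame(phi = phi, psi = psi)
}
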