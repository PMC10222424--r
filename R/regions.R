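#' Tissue region catalogue
#'
#' The phantom distinguishes twelve tissue classes: seven electrically active
#' cardiac regions (sinoatrial node, atria, atrioventricular node, His bundle,
#' bundle branches, Purkinje fibers, ventricles), three passive volume
#' conductors (blood chambers, lungs, torso), the optional charge-sensing
#' electrode layer wrapped around the torso, and the non-conducting fibrous
#' barrier that insulates atria from ventricles everywhere except at the
#' atrioventricular node.
#'
#' @return Character vector of the twelve region names, in canonical order.
#' @export
region_names <- function() {
  c("sinoatrial_node", "atria", "atrioventricular_node", "his_bundle",
    "bundle_branches", "purkinje_fibers", "ventricles", "blood_chamber",
    "lung", "torso", "electrode_layer", "fibrous_barrier")
}

# integer code of a region name (canonical order above)
region_id <- function(name) {
  id <- match(name, region_names())
  if (anyNA(id)) stop("unknown region name: ", paste(name[is.na(id)], collapse = ", "))
  id
}

#' Names of the seven active (excitable) cardiac regions
#' @return Character vector, in activation order.
#' @export
active_regions <- function() region_names()[1:7]

#' Names of the passive volume-conductor regions
#' @return Character vector.
#' @export
passive_regions <- function() {
  c("blood_chamber", "lung", "torso", "electrode_layer")
}

#' Dynamic parameters of the excitable-media model
#'
#' Bundles the coefficients of the two-variable reaction-diffusion model:
#' the cubic source \eqn{u_1 (u_1 - \theta)(\alpha - u_1) - u_2} drives the
#' action potential \eqn{u_1} in active tissue, and
#' \eqn{\epsilon (\beta u_1 - \gamma u_2 - \delta)} drives the gate variable
#' \eqn{u_2}. \eqn{\alpha} is the upper (excited) root of the cubic,
#' \eqn{\theta} the regenerative threshold root, and \eqn{\epsilon} the
#' region-wise excitability. Passive regions carry no source; the fibrous
#' barrier does not conduct at all.
#'
#' All quantities are dimensionless. The defaults are the model's reference
#' parameter set: \eqn{\alpha = 1}, \eqn{\beta = 0.5}, \eqn{\gamma = 1},
#' \eqn{\delta = 0}; excitability 0.003 in the sinoatrial node, 0.015 in
#' atria and atrioventricular node, 0.01 in His bundle and bundle branches,
#' 0.005 in Purkinje fibers and ventricles, 0 in passive tissue; and
#' diffusion coefficients of 0.2 for torso and lung, 0.1 for sinoatrial and
#' atrioventricular nodes, His bundle, bundle branches and ventricles, 0.15
#' for the atria, 0.3 for the Purkinje fibers, 0.7 for the blood chambers
#' and 0.2 for the electrode layer. The default threshold root is
#' \eqn{\theta = 0.1}, which leaves a robust ignition margin at the
#' junctions of the conduction tree under these excitabilities; it can be
#' raised or lowered globally or per region.
#'
#' @param alpha Upper root of the cubic (excited state), default 1.
#' @param beta,gamma,delta Recovery coefficients, defaults 0.5, 1, 0.
#' @param theta Threshold root of the cubic, default 0.1.
#' @param epsilon Named numeric vector of per-region excitabilities;
#'   entries override the defaults region by region.
#' @param diffusion Named numeric vector of per-region diffusion
#'   coefficients; entries override the defaults region by region.
#' @param theta_by_region Optional named numeric vector of per-region
#'   threshold overrides.
#' @return An object of class `dynamic_params`.
#' @export
dynamic_params <- function(alpha = 1, beta = 0.5, gamma = 1, delta = 0,
                           theta = 0.1, epsilon = NULL, diffusion = NULL,
                           theta_by_region = NULL) {
  eps <- c(sinoatrial_node = 0.003, atria = 0.015,
           atrioventricular_node = 0.015, his_bundle = 0.01,
           bundle_branches = 0.01, purkinje_fibers = 0.005,
           ventricles = 0.005, blood_chamber = 0, lung = 0, torso = 0,
           electrode_layer = 0, fibrous_barrier = 0)
  D <- c(sinoatrial_node = 0.1, atria = 0.15, atrioventricular_node = 0.1,
         his_bundle = 0.1, bundle_branches = 0.1, purkinje_fibers = 0.3,
         ventricles = 0.1, blood_chamber = 0.7, lung = 0.2, torso = 0.2,
         electrode_layer = 0.2, fibrous_barrier = 0)
  th <- stats::setNames(rep(theta, 12L), region_names())
  if (!is.null(epsilon)) {
    region_id(names(epsilon))
    eps[names(epsilon)] <- epsilon
  }
  if (!is.null(diffusion)) {
    region_id(names(diffusion))
    D[names(diffusion)] <- diffusion
  }
  if (!is.null(theta_by_region)) {
    region_id(names(theta_by_region))
    th[names(theta_by_region)] <- theta_by_region
  }
  if (any(D < 0)) stop("diffusion coefficients must be non-negative")
  if (D[["fibrous_barrier"]] != 0)
    stop("the fibrous barrier is non-conducting; its diffusion must be 0")
  if (any(eps[passive_regions()] != 0) || eps[["fibrous_barrier"]] != 0)
    stop("passive regions must have zero excitability")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
         epsilon_by_region = eps, diffusion_by_region = D,
         theta_by_region = th),
    class = "dynamic_params")
}

#' Reaction source terms of the excitable-media model
#'
#' Evaluates the local (reaction) part of the model in one tissue region.
#' Active cardiac regions return the cubic source
#' \eqn{u_1 (u_1 - \theta)(\alpha - u_1) - u_2} for the action potential and
#' \eqn{\epsilon (\beta u_1 - \gamma u_2 - \delta)} for the gate variable;
#' passive volume-conductor regions (and the fibrous barrier) return zero
#' sources, so signal can only diffuse through them.
#'
#' @param u1,u2 Action potential and gate variable (scalars or equal-length
#'   vectors).
#' @param region A single region name.
#' @param params A [dynamic_params()] object.
#' @return List with elements `du1` and `du2`.
#' @export
reaction_term <- function(u1, u2, region, params = dynamic_params()) {
  stopifnot(inherits(params, "dynamic_params"), length(region) == 1L)
  id <- region_id(region)
  if (id <= 7L) {
    th <- params$theta_by_region[[region]]
    eps <- params$epsilon_by_region[[region]]
    list(du1 = u1 * (u1 - th) * (params$alpha - u1) - u2,
         du2 = eps * (params$beta * u1 - params$gamma * u2 - params$delta))
  } else {
    z <- rep(0, length(u1))
    list(du1 = z, du2 = z)
  }
}
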