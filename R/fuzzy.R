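# Fuzzy-logic biological controller: fuzzification of strain and
# tissue-composition inputs, Mamdani-style min/max rule evaluation, crisp
# +-1 consequents on bone and cartilage fractions, temporal smoothing and
# element-size scaling of the composition increments.

#' Tissue material constants
#'
#' Young's moduli and Poisson's ratios of the four tissue types. Soft
#' tissue, cartilage and woven bone mix inside callus elements; lamellar
#' bone is reserved for the bone fragments.
#'
#' @return Data frame with columns `tissue`, `E` (MPa), `nu`.
#' @export
tissue_properties <- function() {
  data.frame(
    tissue = c("soft", "cartilage", "woven", "lamellar"),
    E = c(3, 200, 4000, 10000),
    nu = c(0.30, 0.45, 0.36, 0.36),
    stringsAsFactors = FALSE
  )
}

#' Composition to element material properties (rule of mixtures)
#'
#' Young's modulus follows a cubic and Poisson's ratio a linear rule of
#' mixtures over the three callus tissues:
#' \deqn{E = \sum_t E_t c_t^3, \qquad \nu = \sum_t \nu_t c_t.}
#'
#' @param c_soft,c_cart,c_bone Tissue fractions on the unit simplex
#'   (vectorised).
#' @param tissues Tissue constants, see [tissue_properties()].
#' @return List with vectors `E` (MPa) and `nu`.
#' @export
mixture_properties <- function(c_soft, c_cart, c_bone,
                               tissues = tissue_properties()) {
  s <- c_soft + c_cart + c_bone
  if (any(abs(s - 1) > 1e-9) || any(c(c_soft, c_cart, c_bone) < -1e-12)) {
    stop("composition must lie on the unit simplex")
  }
  Et <- stats::setNames(tissues$E, tissues$tissue)
  nt <- stats::setNames(tissues$nu, tissues$tissue)
  list(
    E = Et[["soft"]] * c_soft^3 + Et[["cartilage"]] * c_cart^3 +
      Et[["woven"]] * c_bone^3,
    nu = nt[["soft"]] * c_soft + nt[["cartilage"]] * c_cart +
      nt[["woven"]] * c_bone
  )
}

#' Trapezoidal membership function
#'
#' @param x Input values (vectorised).
#' @param p Breakpoints `c(a, b, c, d)`, non-decreasing: membership rises
#'   linearly on `[a, b]`, is 1 on `[b, c]`, falls on `[c, d]`. Coincident
#'   breakpoints give crisp edges.
#' @return Membership degrees in [0, 1].
#' @export
trapmf <- function(x, p) {
  stopifnot(length(p) == 4, !is.unsorted(p))
  up <- if (p[2] > p[1]) (x - p[1]) / (p[2] - p[1]) else as.numeric(x >= p[1])
  dn <- if (p[4] > p[3]) (p[4] - x) / (p[4] - p[3]) else as.numeric(x <= p[4])
  pmax(0, pmin(1, up, dn))
}

#' Default membership functions
#'
#' Trapezoidal Low/Med/High categories for the four controller input
#' families. Tissue proportions (own and neighbourhood bone/cartilage) are
#' on [0, 1]; the three strain inputs are percentages of the corresponding
#' non-negative strain measure (compressive magnitude of the minimum
#' principal strain, tensile part of the maximum principal strain, and
#' octahedral shear). The strain category boundaries follow the
#' tissue-differentiation threshold literature: direct bone apposition for
#' small deviatoric stimulus, cartilage for moderate compression, fibrous
#' persistence beyond ~15% compression. These breakpoints, together with
#' the element-size coefficient and the smoothing window, are the model's
#' calibration parameters and can be overridden via the config.
#'
#' @return Named list (`tissue`, `eps_min`, `eps_max`, `eps_dist`), each a
#'   list of `Low`/`Med`/`High` trapezoid breakpoints.
#' @export
membership_defaults <- function() {
  big <- 1e6
  list(
    tissue = list(Low = c(0, 0, 0.15, 0.4),
                  Med = c(0.25, 0.5, 0.6, 0.8),
                  High = c(0.6, 0.8, 1, 1)),
    eps_min = list(Low = c(0, 0, 3, 8),
                   Med = c(4, 8, 18, 28),
                   High = c(18, 28, big, big)),
    eps_max = list(Low = c(0, 0, 2, 6),
                   Med = c(4, 8, 12, 17),
                   High = c(12, 17, big, big)),
    eps_dist = list(Low = c(0, 0, 8, 18),
                    Med = c(8, 18, 25, 35),
                    High = c(25, 35, big, big))
  )
}

# variable name -> membership-function family
.mf_family <- c(bone = "tissue", cart = "tissue", nbone = "tissue",
                ncart = "tissue",
                eps_min = "eps_min", eps_max = "eps_max",
                eps_dist = "eps_dist")

#' Fuzzify an input variable
#'
#' @param x Input values: tissue fractions on [0, 1] or strains in percent.
#' @param variable One of `"bone"`, `"cart"`, `"nbone"`, `"ncart"`,
#'   `"eps_min"`, `"eps_max"`, `"eps_dist"`.
#' @param mfs Membership-function set, see [membership_defaults()].
#' @return Matrix with one row per input and columns `Low`, `Med`, `High`.
#' @export
fuzzify <- function(x, variable, mfs = membership_defaults()) {
  fam <- .mf_family[variable]
  if (is.na(fam)) stop("unknown controller variable '", variable, "'")
  set <- mfs[[fam]]
  out <- vapply(c("Low", "Med", "High"),
                function(cat) trapmf(x, set[[cat]]),
                numeric(length(x)))
  matrix(out, ncol = 3, dimnames = list(NULL, c("Low", "Med", "High")))
}

#' The four biological rules
#'
#' The default rule table: intramembranous ossification, chondrogenesis
#' (two antecedent variants that act simultaneously), cartilage
#' calcification and endochondral ossification. Antecedent clauses are
#' conjunctions (min); a clause listing several categories takes their
#' maximum. Consequents are crisp increments on bone and cartilage
#' fractions. The two chondrogenesis rows are gated off during the first
#' `chondro_delay` iterations of a healing run to prevent non-physiological
#' periosteal cartilage.
#'
#' @return List of rules, each with `name`, `clauses` (named list of
#'   category vectors), `d_bone`, `d_cart`, `delayed`.
#' @export
rule_table_default <- function() {
  list(
    list(name = "intramembranous_ossification",
         clauses = list(cart = "Low", nbone = c("Med", "High"),
                        eps_max = "Med", eps_dist = "Low"),
         d_bone = 1, d_cart = 0, delayed = FALSE),
    list(name = "chondrogenesis_nbone",
         clauses = list(bone = "Low", nbone = c("Med", "High"),
                        eps_min = "Med", eps_max = "Low", eps_dist = "Low"),
         d_bone = 0, d_cart = 1, delayed = TRUE),
    list(name = "chondrogenesis_ncart",
         clauses = list(bone = "Low", ncart = c("Med", "High"),
                        eps_min = "Med", eps_max = "Low", eps_dist = "Low"),
         d_bone = 0, d_cart = 1, delayed = TRUE),
    list(name = "cartilage_calcification",
         clauses = list(bone = "High", cart = "Low", nbone = "High"),
         d_bone = 1, d_cart = -1, delayed = FALSE),
    list(name = "endochondral_ossification",
         clauses = list(cart = c("Med", "High"), nbone = c("Med", "High"),
                        eps_min = "Low"),
         d_bone = 1, d_cart = -1, delayed = FALSE)
  )
}

#' Degree of activation of one rule
#'
#' AND across clauses is the minimum; OR within a clause ("Med or High") is
#' the maximum; variables absent from the rule do not constrain it.
#'
#' @param rule A rule from [rule_table_default()].
#' @param fuzzified Named list of fuzzified membership matrices, one per
#'   variable appearing in the rule (see [fuzzify()]).
#' @return Activation degree(s) in [0, 1].
#' @export
rule_activation <- function(rule, fuzzified) {
  act <- NULL
  for (var in names(rule$clauses)) {
    memb <- fuzzified[[var]]
    if (is.null(memb)) stop("no memberships supplied for variable '", var, "'")
    cats <- rule$clauses[[var]]
    cm <- memb[, cats[1]]
    for (cat in cats[-1]) cm <- pmax(cm, memb[, cat])
    act <- if (is.null(act)) cm else pmin(act, cm)
  }
  unname(act)
}

#' Assemble controller inputs from a strain state and composition
#'
#' Strain inputs are the non-negative stimuli the membership functions are
#' defined over, in percent: the magnitude of the compressive (minimum)
#' principal strain, the tensile part of the maximum principal strain, and
#' the octahedral shear strain. Neighbourhood inputs are the maxima of
#' bone/cartilage fractions over the share-a-node neighbour set, with
#' bone-fragment elements counting as fully ossified (`c_bone` = 1).
#'
#' @param strains Strain data frame for the callus elements (rows align
#'   with `adjacency$callus_elements`), see [recover_strains()].
#' @param c_bone,c_cart Current (smoothed) fractions per callus element.
#' @param adjacency A [build_adjacency()] map.
#' @param region Element region labels of the full mesh.
#' @return List of input vectors: `eps_min`, `eps_max`, `eps_dist` (percent),
#'   `bone`, `cart`, `nbone`, `ncart`.
#' @export
controller_inputs <- function(strains, c_bone, c_cart, adjacency, region) {
  callus <- adjacency$callus_elements
  stopifnot(nrow(strains) == length(callus),
            length(c_bone) == length(callus),
            length(c_cart) == length(callus))
  # composition over *all* elements for neighbourhood lookups
  nelem <- length(region)
  cb_all <- numeric(nelem); cc_all <- numeric(nelem)
  cb_all[region == "bone_fragment"] <- 1
  cb_all[callus] <- c_bone
  cc_all[callus] <- c_cart
  nbone <- vapply(adjacency$neighbors, function(ix) max(cb_all[ix]), 0)
  ncart <- vapply(adjacency$neighbors, function(ix) max(cc_all[ix]), 0)
  list(
    eps_min = 100 * pmax(-strains$eps_min, 0),
    eps_max = 100 * pmax(strains$eps_max, 0),
    eps_dist = 100 * strains$eps_dist,
    bone = c_bone, cart = c_cart, nbone = nbone, ncart = ncart
  )
}

#' One un-smoothed composition update
#'
#' Evaluates all rules on the fuzzified inputs, sums their bone/cartilage
#' increments, scales by the element-size coefficient
#' `kappa * ref_length / char_length` (smaller elements change
#' proportionally faster, keeping the ossification-front speed
#' mesh-independent), adds the increments to the running un-smoothed
#' composition and projects back onto the unit simplex. If the summed
#' increments would push `c_bone + c_cart` past 1 they are scaled down
#' jointly, preserving their ratio; cartilage is clamped at zero.
#' Chondrogenesis rules are inactive while `iteration <= chondro_delay`.
#'
#' @param inputs Controller inputs, see [controller_inputs()].
#' @param c_bone,c_cart Current un-smoothed fractions per element.
#' @param rules Rule table.
#' @param kappa Element-size rate coefficient (per iteration).
#' @param char_length Element characteristic lengths, mm.
#' @param ref_length Reference element length, mm (0.35 by default).
#' @param iteration Current iteration index (>= 1).
#' @param chondro_delay Number of initial iterations with chondrogenesis
#'   disabled.
#' @param mfs Membership functions.
#' @return List: updated `c_bone`, `c_cart`, `c_soft`, and `activation`
#'   (matrix, one column per rule).
#' @export
compose_update <- function(inputs, c_bone, c_cart, rules = rule_table_default(),
                           kappa, char_length, ref_length = 0.35,
                           iteration, chondro_delay = 7,
                           mfs = membership_defaults()) {
  stopifnot(iteration >= 1)
  if (any(c_bone < -1e-12 | c_cart < -1e-12 | c_bone + c_cart > 1 + 1e-9)) {
    stop("composition outside the unit simplex on entry")
  }
  vars <- unique(unlist(lapply(rules, function(r) names(r$clauses))))
  fuzz <- lapply(stats::setNames(vars, vars),
                 function(v) fuzzify(inputs[[v]], v, mfs))
  n <- length(c_bone)
  act <- matrix(0, n, length(rules),
                dimnames = list(NULL, vapply(rules, `[[`, "", "name")))
  db <- numeric(n); dc <- numeric(n)
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (r$delayed && iteration <= chondro_delay) next
    a <- rule_activation(r, fuzz)
    act[, k] <- a
    db <- db + a * r$d_bone
    dc <- dc + a * r$d_cart
  }
  scale <- kappa * ref_length / char_length
  db <- db * scale
  dc <- dc * scale
  # joint scaling onto the simplex boundary keeps the increment ratio
  tot <- db + dc
  room <- 1 - (c_bone + c_cart)
  over <- tot > room & tot > 0
  f <- ifelse(over, pmax(room, 0) / tot, 1)
  b1 <- unname(pmin(pmax(c_bone + f * db, 0), 1))
  c1 <- unname(pmin(pmax(c_cart + f * dc, 0), 1))
  list(c_bone = b1, c_cart = c1, c_soft = 1 - b1 - c1, activation = act)
}

#' Temporal smoothing of the composition
#'
#' The composition used for material properties (and as controller input)
#' at iteration i is the arithmetic mean of the un-smoothed compositions of
#' the last `min(N, i)` iterations.
#'
#' @param buffer Numeric matrix of un-smoothed values, one row per stored
#'   iteration (most recent last), one column per element.
#' @return Vector of smoothed values per element.
#' @export
temporal_smooth <- function(buffer) {
  if (is.null(dim(buffer))) buffer <- matrix(buffer, nrow = 1)
  if (nrow(buffer) == 0) stop("smoothing buffer is empty")
  colMeans(buffer)
}
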