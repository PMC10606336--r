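#' Shannon entropy of a discrete distribution
#'
#' \eqn{H(p) = -\sum_i p_i \log_2 p_i} in bits, with
#' \eqn{0 \cdot \log_2 0 := 0} by continuity. The result lies in
#' \eqn{[0, \log_2 n]} and attains the maximum only for the uniform
#' distribution.
#'
#' @param p Numeric probability vector: entries >= 0 summing to 1 (within
#'   1e-6).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))        # 1
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5
#' @export
shannon_entropy <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("invalid distribution: empty or non-numeric", call. = FALSE)
  if (any(p < 0))
    stop("invalid distribution: negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop("invalid distribution: entries must sum to 1 (got ",
         format(sum(p)), ")", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Arrival entropy of a care network
#'
#' The arrival entropy measures the uncertainty about *where* demand lands
#' in the system. The relative demand of unit *i* is
#' \eqn{d_i = \mathrm{Eff}\lambda_i / \sum_j \mathrm{Eff}\lambda_j}; the
#' arrival entropy is the Shannon entropy of \eqn{d}, and its maximum —
#' attained when demand is spread uniformly, \eqn{d_i = 1/N} — is
#' \eqn{\log_2 N}. Pooling units reduces \eqn{N} and therefore the maximum.
#'
#' @param x A [care_network()] (effective arrival rates are computed via
#'   the traffic equations) or a numeric vector of effective arrival rates.
#' @return An object of class `arrival_entropy_report`: list with
#'   `relative_demand`, `entropy_bits`, `max_entropy_bits` and `n_units`.
#' @examples
#' arrival_entropy(c(4.0, 1.2, 0.2, 0.9, 2.7))  # 1.88 bits, max 2.32
#' @export
arrival_entropy <- function(x) {
  eff <- if (inherits(x, "care_network")) effective_arrival_rates(x)
         else as.numeric(x)
  if (any(eff < 0)) stop("invalid distribution: negative arrival rates", call. = FALSE)
  total <- sum(eff)
  if (total <= 0)
    stop("invalid distribution: all arrival rates are zero", call. = FALSE)
  d <- eff / total
  structure(list(
    relative_demand = d,
    entropy_bits = shannon_entropy(d),
    max_entropy_bits = log2(length(d)),
    n_units = length(d)
  ), class = "arrival_entropy_report")
}

#' @export
print.arrival_entropy_report <- function(x, ...) {
  cat(sprintf("<arrival_entropy> %.2f bits (max %.2f over %d units)\n",
              x$entropy_bits, x$max_entropy_bits, x$n_units))
  invisible(x)
}

#' Patient-class position matrix
#'
#' Row *k* gives the probability distribution of patient class *k*'s next
#' placement over the units (optionally including a `"home"` pseudo-position
#' for discharge). Each row must sum to 1.
#'
#' @param probabilities Numeric matrix (classes x positions) with column
#'   names; or an object coercible to one.
#' @param classes Optional class labels (rownames).
#' @return A `position_matrix` object.
#' @export
position_matrix <- function(probabilities, classes = NULL) {
  P <- as.matrix(probabilities)
  if (!is.null(classes)) rownames(P) <- classes
  if (is.null(rownames(P))) rownames(P) <- paste0("class", seq_len(nrow(P)))
  if (any(P < 0) || any(P > 1))
    stop("position probabilities must lie in [0, 1]", call. = FALSE)
  bad <- abs(rowSums(P) - 1) > 1e-6
  if (any(bad))
    stop("position rows must sum to 1; offending class(es): ",
         paste(rownames(P)[bad], collapse = ", "), call. = FALSE)
  structure(P, class = c("position_matrix", "matrix"))
}

#' Positional entropy of patient classes
#'
#' Per class *k*, the entropy of its placement distribution
#' \eqn{H_k = -\sum_i P_{ki} \log_2 P_{ki}}; the system positional entropy
#' is the sum over classes, \eqn{H_{ps} = \sum_k H_k}. The maximum variant
#' replaces each row by the uniform distribution over the class's declared
#' support (its nonzero positions), giving \eqn{\log_2 |supp(k)|} per
#' class.
#'
#' @param positions A [position_matrix()].
#' @return List of class `positional_entropy_report` with `per_class`,
#'   `entropy_bits`, `max_per_class`, `max_entropy_bits`.
#' @export
positional_entropy <- function(positions) {
  if (!inherits(positions, "position_matrix"))
    positions <- position_matrix(positions)
  per <- apply(unclass(positions), 1, shannon_entropy)
  supp <- apply(unclass(positions), 1, function(r) sum(r > 0))
  maxper <- log2(pmax(supp, 1))
  names(maxper) <- rownames(positions)
  structure(list(per_class = per, entropy_bits = sum(per),
                 max_per_class = maxper, max_entropy_bits = sum(maxper)),
            class = "positional_entropy_report")
}

#' @export
print.positional_entropy_report <- function(x, ...) {
  cat(sprintf("<positional_entropy> %.2f bits (max %.2f) over %d class(es)\n",
              x$entropy_bits, x$max_entropy_bits, length(x$per_class)))
  invisible(x)
}

#' Derive a position matrix from a feed-forward network
#'
#' Builds a default set of patient classes — one per external entry stream
#' (each unit with positive external arrivals) — and sets each class's
#' placement distribution to the one-step routing of its entry unit. Mass
#' not routed to any unit goes to a `"home"` pseudo-position (discharge).
#' Networks with cyclic routing have no such canonical one-step reading;
#' supply a [position_matrix()] directly in that case.
#'
#' @param network A feed-forward [care_network()].
#' @param home Label of the discharge pseudo-position.
#' @return A [position_matrix()] with one row per entry class.
#' @examples
#' derive_position_matrix(perinatology_network())
#' @export
derive_position_matrix <- function(network, home = "home") {
  stopifnot(inherits(network, "care_network"))
  if (is.null(topological_order(network$routing)))
    stop("cyclic networks are unsupported for derivation; supply a position_matrix",
         call. = FALSE)
  entries <- which(network$units$external_rate > 0)
  if (!length(entries))
    stop("network has no external entry streams", call. = FALSE)
  ids <- unit_ids(network)
  R <- network$routing
  rows <- t(vapply(entries, function(i) {
    r <- R[i, ]
    c(r, max(0, 1 - sum(r)))
  }, numeric(length(ids) + 1)))
  colnames(rows) <- c(ids, home)
  rownames(rows) <- paste0("entry_", ids[entries])
  keep <- colSums(rows) > 0 | colnames(rows) != home
  position_matrix(rows[, keep, drop = FALSE])
}

#' Decision-structure entropy
#'
#' Each decision maker *a* processes information from sources *b* with
#' probabilities \eqn{P_{ab}} (rows summing to 1). The maker's entropy is
#' \eqn{H_a = -\sum_b P_{ab}\log_2 P_{ab}} and the structure's entropy is
#' the sum over makers, \eqn{H_{ds} = \sum_a H_a}. With uniform source
#' probabilities \eqn{H_a = \log_2(\#\mathrm{sources})}. Makers with no
#' sources contribute 0 bits.
#'
#' @param structure A [decision_structure()].
#' @return List of class `decision_entropy_report` with `per_maker` and
#'   `entropy_bits`.
#' @export
decision_entropy <- function(structure) {
  stopifnot(inherits(structure, "decision_structure"))
  per <- vapply(structure$sources, function(p) {
    if (!length(p)) 0 else shannon_entropy(p)
  }, numeric(1))
  structure(list(per_maker = per, entropy_bits = sum(per)),
            class = "decision_entropy_report")
}

#' @export
print.decision_entropy_report <- function(x, ...) {
  cat(sprintf("<decision_entropy> %.2f bits over %d decision maker(s)\n",
              x$entropy_bits, length(x$per_maker)))
  invisible(x)
}

#' Total system entropy
#'
#' The total uncertainty of a care-system design is the sum of its arrival,
#' positional and decision-structure entropies (all in bits). Report
#' objects may be passed directly; their `entropy_bits` component is used.
#' The published summary convention sums the *maximum* arrival and
#' positional entropies with the decision entropy of the chosen
#' coordination strategy; pass the `max_entropy_bits` values (or the report
#' objects with `use_max = TRUE`) for that convention.
#'
#' @param arrival,positional,decision Numbers in bits, or the corresponding
#'   report objects.
#' @param use_max For report objects, take the maximum-entropy variant of
#'   the arrival and positional components.
#' @return Total entropy in bits.
#' @examples
#' total_entropy(2.32, 4.16, 8)  # 14.48
#' @export
total_entropy <- function(arrival, positional, decision, use_max = FALSE) {
  pick <- function(x, kind) {
    if (is.numeric(x)) return(sum(x))
    if (use_max && !is.null(x$max_entropy_bits)) return(x$max_entropy_bits)
    if (!is.null(x$entropy_bits)) return(x$entropy_bits)
    stop("cannot interpret ", kind, " component", call. = FALSE)
  }
  pick(arrival, "arrival") + pick(positional, "positional") +
    pick(decision, "decision")
}
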