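#' Enumerate eQTL activity configurations
#'
#' A configuration is a binary vector over tissues indicating in which
#' tissues an eQTL is active; every nonzero vector is one alternative
#' hypothesis (the all-zero vector is the global null and is excluded).
#' Configurations are returned in deterministic order: by the number of
#' active tissues `q`, then lexicographically.
#'
#' @param S Number of tissues (1 to 20; full enumeration has `2^S - 1`
#'   terms, so larger S must use the lite statistic instead).
#' @return Integer matrix with `2^S - 1` rows and S columns of 0/1,
#'   rownames like `"101"`.
#' @examples
#' enumerate_configs(3)
#' @export
enumerate_configs <- function(S) {
  stopifnot(S >= 1L)
  if (S > 20L) {
    stop("full configuration enumeration is impractical for S > 20; use lite weights")
  }
  m <- as.matrix(expand.grid(rep(list(0:1), S))[, S:1, drop = FALSE])
  m <- m[-1L, , drop = FALSE]
  q <- rowSums(m)
  key <- do.call(paste0, as.data.frame(m))
  ord <- order(q, key, method = "radix")
  m <- m[ord, , drop = FALSE]
  dimnames(m) <- list(key[ord], paste0("tissue", seq_len(S)))
  m
}

config_labels <- function(configs) rownames(configs)

#' Default prior weights on configurations
#'
#' Puts prior weight 1/S on each possible number of active tissues
#' `q = 1, ..., S` and, given q, equal weight on all `choose(S, q)`
#' configurations, i.e. `eta = 1 / (S * choose(S, q))`.
#'
#' @param S Number of tissues.
#' @return Tibble with columns `config` (binary-string label), `q` and
#'   `eta`, in [enumerate_configs()] order.
#' @examples
#' default_weights(2)
#' @export
default_weights <- function(S) {
  cfg <- enumerate_configs(S)
  q <- rowSums(cfg)
  tibble::tibble(config = rownames(cfg), q = as.integer(q),
                 eta = 1 / (S * choose(S, q)))
}

#' Lite prior weights on configurations
#'
#' Weight 0.5 on the consistent configuration (active in all tissues) and
#' 0.5 split equally over the S singleton configurations; all other
#' configurations get weight 0. Because only `S + 1` configurations carry
#' mass, the lite statistic remains practical for very large S (heterogeneity
#' among shared tissues is instead absorbed by the wider lite grid).
#'
#' @param S Number of tissues.
#' @return Tibble with columns `config`, `q`, `eta`.
#' @export
lite_weights <- function(S) {
  cfg <- enumerate_configs(S)
  q <- rowSums(cfg)
  eta <- numeric(nrow(cfg))
  eta[q == S] <- 0.5
  eta[q == 1] <- 0.5 / S
  if (S == 1L) eta <- 1
  tibble::tibble(config = rownames(cfg), q = as.integer(q), eta = eta)
}

#' Configuration prior weights
#'
#' @param S Number of tissues.
#' @param kind `"default"` or `"lite"`; see [default_weights()] and
#'   [lite_weights()].
#' @return Tibble with columns `config`, `q`, `eta`.
#' @export
config_weights <- function(S, kind = c("default", "lite")) {
  kind <- match.arg(kind)
  if (kind == "default") default_weights(S) else lite_weights(S)
}

validate_weights <- function(eta) {
  if (any(eta < 0) || abs(sum(eta) - 1) > 1e-8) {
    stop("configuration weights must be nonnegative and sum to 1")
  }
  eta
}
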