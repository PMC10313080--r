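#' GradNorm adaptive task-weight state
#'
#' Holds the per-task loss weights omega_i(t) (initialized to 1), the
#' initial losses L_i(0) (recorded at the first step), the balancing
#' strength alpha, and the Adam state of the independent optimizer that
#' updates the weights. After every step the weights are renormalized so
#' that sum_i omega_i = N_task.
#'
#' @param n_tasks number of tasks (default 2).
#' @param alpha restoring-force strength (default 1.5).
#' @param lr learning rate of the independent weight optimizer (Adam).
#' @return a `gradnorm_state`.
#' @export
gradnorm_state <- function(n_tasks = 2, alpha = 1.5, lr = 0.025) {
  structure(list(
    n_tasks = n_tasks, alpha = alpha, lr = lr,
    omega = rep(1, n_tasks), L0 = NULL, t = 0L,
    adam_m = rep(0, n_tasks), adam_v = rep(0, n_tasks),
    last = NULL), class = "gradnorm_state")
}

#' Per-task gradient norms on the shared layer
#'
#' G_W^(i) = || d(omega_i L_i) / dW ||_2, the L2 norm over all entries of
#' the shared layer's parameters of the single-task weighted loss gradient.
#' `shared_grads` holds, per task, the gradient of the *unweighted* loss
#' L_i with respect to the shared layer (any nested list of numeric
#' arrays); linearity gives the weighted norm as omega_i * ||dL_i/dW||.
#'
#' @param state a [gradnorm_state()].
#' @param shared_grads list (one element per task) of gradients w.r.t. the
#'   shared layer.
#' @return numeric vector of per-task gradient norms.
#' @export
task_gradient_norms <- function(state, shared_grads) {
  if (length(shared_grads) != state$n_tasks) stop("one gradient per task required")
  raw <- vapply(shared_grads, function(g) sqrt(tree_sumsq(g)), numeric(1))
  if (any(!is.finite(raw)))
    stop("non-finite shared-layer gradient: a task loss appears detached from W")
  state$omega * raw
}

#' Relative inverse training rates
#'
#' Ltilde_i(t) = L_i(t) / L_i(0) and r_i(t) = Ltilde_i(t) / Avg(Ltilde);
#' the returned rates average to exactly 1. Tasks whose loss has decayed
#' less than average (r_i > 1) are training slower and receive a larger
#' gradient-norm target.
#'
#' @param state a `gradnorm_state` with recorded initial losses.
#' @param losses current per-task losses.
#' @return per-task rates r_i(t).
#' @export
inverse_training_rates <- function(state, losses) {
  if (is.null(state$L0)) stop("initial losses not recorded yet")
  if (any(state$L0 <= 0)) stop("initial losses must be > 0")
  ltilde <- losses / state$L0
  ltilde / mean(ltilde)
}

#' GradNorm balancing loss
#'
#' L_grad = sum_i | G_i - Gbar * r_i^alpha |, with Gbar = Avg(G_i); the
#' target Gbar * r_i^alpha is treated as a constant (no gradient flows
#' through it).
#'
#' @param G per-task gradient norms.
#' @param r per-task relative inverse training rates.
#' @param alpha balancing strength.
#' @return scalar L_grad.
#' @export
gradnorm_loss <- function(G, r, alpha = 1.5) {
  if (length(G) != length(r)) stop("G and r must have the same length")
  sum(abs(G - mean(G) * r^alpha))
}

#' Renormalize task weights
#'
#' Scales the weights so that sum_i omega_i = N_task, preserving their
#' proportions. Non-positive weights (possible after an aggressive update)
#' are clamped to a small floor (1e-4) first.
#'
#' @param state a `gradnorm_state`.
#' @return the state with renormalized weights.
#' @export
renormalize <- function(state) {
  w <- state$omega
  if (any(w <= 0)) {
    grn_log("clamping non-positive task weight(s) to 1e-4 before renormalizing")
    w <- pmax(w, 1e-4)
  }
  state$omega <- w * state$n_tasks / sum(w)
  state
}

#' One GradNorm step
#'
#' Executes the per-iteration procedure: with the current weights, the
#' total loss is L(t) = sum_i omega_i L_i(t); the per-task gradient norms
#' G_i on the shared layer and the relative inverse training rates r_i are
#' computed; L_grad = sum_i |G_i - Gbar r_i^alpha| is minimized one Adam
#' step in the weights (the target Gbar r_i^alpha held constant, so
#' dL_grad/domega_i = sign(G_i - target_i) * G_i / omega_i by linearity of
#' G_i in omega_i); the weights are then renormalized to sum to N_task.
#' Initial losses are recorded at the first call.
#'
#' @param state a [gradnorm_state()].
#' @param losses per-task unweighted losses L_i(t).
#' @param shared_grads per-task gradients of the unweighted losses w.r.t.
#'   the shared layer (see [task_gradient_norms()]).
#' @return list(state = updated state, total = total loss under the
#'   weights in force this step, omega = those weights).
#' @export
gradnorm_step <- function(state, losses, shared_grads) {
  if (!inherits(state, "gradnorm_state")) stop("state must be a gradnorm_state")
  if (length(losses) != state$n_tasks)
    stop("expected ", state$n_tasks, " task losses, got ", length(losses))
  if (is.null(state$L0)) state$L0 <- losses
  omega_t <- state$omega                      # weights in force for L(t)
  total <- sum(omega_t * losses)
  G <- task_gradient_norms(state, shared_grads)
  r <- inverse_training_rates(state, losses)
  target <- mean(G) * r^state$alpha
  lgrad <- sum(abs(G - target))
  grad_omega <- sign(G - target) * ifelse(omega_t > 0, G / omega_t, 0)
  # independent Adam step on the weights
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$adam_m <- b1 * state$adam_m + (1 - b1) * grad_omega
  state$adam_v <- b2 * state$adam_v + (1 - b2) * grad_omega^2
  mhat <- state$adam_m / (1 - b1^state$t)
  vhat <- state$adam_v / (1 - b2^state$t)
  state$omega <- omega_t - state$lr * mhat / (sqrt(vhat) + eps)
  state <- renormalize(state)
  state$last <- list(G = G, r = r, lgrad = lgrad)
  list(state = state, total = total, omega = omega_t)
}
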