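# Executable fixtures: a bat-habitat network, the intransitive
# rock-paper-scissors game, and the three-state boreal succession cycle.
# The bat conditionals other than the riparian prior are hypothetical values
# (no formal probability model exists for the species); they are fixed,
# documented constants so that every example is reproducible, with an opt-in
# flag that redraws them from the current RNG for property testing.

#' Bat-habitat network fixture
#'
#' A three-node network for the habitat quality of a riparian-woodland bat:
#' `riparian` (presence of gallery riparian forest, prior 0.1), `woodland`
#' (presence of low-lying woodland/scrub/savanna) and `habitat` (good/poor)
#' conditional on both. Only the riparian prior is an established value; the
#' remaining entries are synthetic placeholders chosen to reflect a species
#' that favours riparian corridors within wooded environments.
#'
#' @param riparian_prior P(riparian present), default 0.1.
#' @param woodland_prior P(woodland present), default 0.5 (placeholder).
#' @param p_good P(habitat good) for the four parent configurations in
#'   [expand.grid()] order over (riparian, woodland):
#'   (present, present), (absent, present), (present, absent),
#'   (absent, absent). Placeholder defaults `c(0.9, 0.3, 0.6, 0.05)`.
#' @param phases Phase matrix (4 x 2, radians) for the habitat table, or a
#'   scalar; default 0 (classical network).
#' @param habitat_rotation Measurement-basis rotation for the habitat node
#'   (radians), used by [sequential_condition()]; default 0.
#' @param randomize Redraw `woodland_prior` and `p_good` from the current RNG
#'   (placeholder randomization for property tests).
#' @return A [qbn()] object.
#' @export
#' @examples
#' net <- bat_network()
#' classical_joint(net, c(riparian = "present", woodland = "present",
#'                        habitat = "good"))
bat_network <- function(riparian_prior = 0.1, woodland_prior = 0.5,
                        p_good = c(0.9, 0.3, 0.6, 0.05), phases = 0,
                        habitat_rotation = 0, randomize = FALSE) {
  if (randomize) {
    woodland_prior <- stats::runif(1, 0.05, 0.95)
    p_good <- stats::runif(4, 0.02, 0.98)
  }
  qbn(
    qnode("riparian", c("present", "absent"),
          probs = c(riparian_prior, 1 - riparian_prior)),
    qnode("woodland", c("present", "absent"),
          probs = c(woodland_prior, 1 - woodland_prior)),
    qnode("habitat", c("good", "poor"), parents = c("riparian", "woodland"),
          probs = cbind(p_good, 1 - p_good), phases = phases,
          rotation = habitat_rotation)
  )
}

#' Rock-paper-scissors network fixture
#'
#' The classic intransitive two-player game as a three-node network: uniform
#' move priors for both players and a deterministic outcome table (rock beats
#' scissors, scissors beats paper, paper beats rock). Specifying a single
#' move conveys no information about the outcome (the network is
#' "solution-incomplete": [information_gain()] is exactly 0), while
#' specifying both moves makes the outcome certain.
#'
#' @return A [qbn()] object with nodes `p1`, `p2`, `outcome`.
#' @export
roshambo_network <- function() {
  moves <- c("rock", "paper", "scissors")
  beats <- c(rock = "scissors", paper = "rock", scissors = "paper")
  grid <- expand.grid(p1 = moves, p2 = moves, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  probs <- t(apply(grid, 1, function(row) {
    if (row[["p1"]] == row[["p2"]]) c(0, 0, 1)
    else if (beats[[row[["p1"]]]] == row[["p2"]]) c(1, 0, 0)
    else c(0, 1, 0)
  }))
  qbn(
    qnode("p1", moves, probs = rep(1 / 3, 3)),
    qnode("p2", moves, probs = rep(1 / 3, 3)),
    qnode("outcome", c("p1_wins", "p2_wins", "draw"),
          parents = c("p1", "p2"), probs = probs)
  )
}

#' Dominance digraph of rock-paper-scissors
#'
#' The cyclic dominance relation rock -> scissors -> paper -> rock as a
#' transition graph ("x -> y" meaning x beats y), whose single directed
#' 3-cycle is the signature of intransitivity.
#'
#' @return A [transition_graph()].
#' @export
roshambo_dominance_graph <- function() {
  transition_graph(
    c("rock", "paper", "scissors"),
    data.frame(from = c("rock", "scissors", "paper"),
               to = c("scissors", "paper", "rock"),
               label = c("blunts", "cuts", "covers"),
               p = 1)
  )
}

#' Boreal black-spruce succession cycle fixture
#'
#' The three-state intransitive circuit of boreal forest development under
#' permafrost disturbance: black spruce forest becomes bog under thermokarst
#' (permafrost thaw-collapse); the bog becomes shrubland under permafrost and
#' peat aggradation; the shrubland returns to black spruce forest under
#' further aggradation with tree regeneration. Transition probabilities are
#' not established quantities; the default treats each labelled transition as
#' certain once its disturbance occurs (`p = 1`).
#'
#' @param p Edge probability (scalar or length-3, in `(0, 1]`).
#' @param theta Edge amplitude phase(s) in radians.
#' @return A [transition_graph()] with states `black_spruce`, `bog`,
#'   `shrubland`.
#' @export
#' @examples
#' g <- spruce_graph()
#' apply_disturbance_sequence(g, "black_spruce",
#'   c("thermokarst", "permafrost_peat_aggradation",
#'     "aggradation_tree_regeneration"))
spruce_graph <- function(p = 1, theta = 0) {
  transition_graph(
    c("black_spruce", "bog", "shrubland"),
    data.frame(from = c("black_spruce", "bog", "shrubland"),
               to = c("bog", "shrubland", "black_spruce"),
               label = c("thermokarst", "permafrost_peat_aggradation",
                         "aggradation_tree_regeneration"),
               p = p, theta = theta)
  )
}

#' Write a named fixture to disk
#'
#' Emits the `bat` or `roshambo` network (JSON network dialect) or the
#' `spruce` transition graph (JSON graph dialect). Identical parameters and
#' seed produce byte-identical files.
#'
#' @param name One of `"bat"`, `"roshambo"`, `"spruce"`.
#' @param path Output file path.
#' @param params Named list of parameter overrides passed to the fixture
#'   constructor.
#' @param seed Optional integer seed (only consulted when `randomize` is
#'   among `params`).
#' @return The path, invisibly.
#' @export
emit_fixture <- function(name, path, params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obj <- switch(name,
    bat = do.call(bat_network, params),
    roshambo = do.call(roshambo_network, params),
    spruce = do.call(spruce_graph, params),
    stop(sprintf("unknown fixture '%s' (expected bat, roshambo or spruce)", name),
         call. = FALSE)
  )
  if (inherits(obj, "qbn")) write_network(obj, path) else write_graph(obj, path)
  invisible(path)
}
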