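# Shared fixtures, built in code. The default simulated troop is cached per
# test run because several files exercise the same study.

.fixtures <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- group_config(seed = 2)
    g <- generate_group(cfg)
    .fixtures$config <- cfg
    .fixtures$group <- g
    .fixtures$study <- simulate_study(g$roster, g$truth, effect_config(), cfg)
  }
  list(config = .fixtures$config, roster = .fixtures$group$roster,
       truth = .fixtures$study$truth, study = .fixtures$study)
}

default_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    fx <- default_study()
    .fixtures$pipeline <- groom_pipeline(
      fx$study$events, fx$study$scans, fx$study$sessions, fx$roster,
      fit = TRUE, n_randomizations = 0)
  }
  .fixtures$pipeline
}

# small troop for fast simulation-based tests
small_config <- function(seed = 1, seasons = 1, hours = 4)
  group_config(n_females = 6, matriline_sizes = c(3, 2, 1),
               seasons = seasons, focal_hours_per_female = hours,
               seed = seed)

all_ordered_pairs <- function(ids) {
  g <- expand.grid(groomee = ids, groomer = ids, stringsAsFactors = FALSE)
  g <- g[g$groomer != g$groomee, c("groomer", "groomee")]
  g[order(g$groomer, g$groomee), ]
}

# minimal hand-built event log rows
event_row <- function(behavior, actor, recipient, start, end = NA,
                      season = "1", session = "s1", focal = actor) {
  data.frame(season = season, session_id = session, focal_id = focal,
             actor_id = actor, recipient_id = recipient,
             behavior = behavior, start = start, end = end,
             stringsAsFactors = FALSE)
}

# counts matrix with ids from named wins: m3(A_beats_B = 3, ...)
counts_matrix <- function(ids, wins) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (w in wins) m[w[[1]], w[[2]]] <- w[[3]]
  m
}

# perfectly decided linear 3-individual matrix (A > B > C)
perfect3 <- function(k = 5)
  counts_matrix(c("A", "B", "C"),
                list(list("A", "B", k), list("A", "C", k), list("B", "C", k)))
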