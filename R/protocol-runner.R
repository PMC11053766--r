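#' Load a protocol pool from a JSON file
#'
#' A pool file holds every protocol prepared before experimentation, each an
#' ordered list of parameterized scenes.  Schema:
#' \code{{"protocols": [{"name": ..., "scenes": [{"id": ..., "param": ...}]}]}}.
#' A scene parameter of \code{"0"} means no extra configuration.
#'
#' @param path JSON file path
#' @return list of \linkS4class{Protocol} objects
#' @export
loadProtocolPool <- function(path) {
  if (!file.exists(path)) stop("protocol pool file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  protos <- raw$protocols
  if (is.null(protos) || length(protos) == 0)
    stop("protocol pool is empty")
  pool <- lapply(protos, function(p) {
    scenes <- do.call(rbind, lapply(p$scenes, function(s)
      data.frame(id = as.character(s$id),
                 param = as.character(s$param %||% "0"),
                 stringsAsFactors = FALSE)))
    new("Protocol", name = as.character(p$name), scenes = scenes)
  })
  nm <- vapply(pool, function(p) p@name, character(1))
  if (anyDuplicated(nm)) stop("duplicate protocol names in pool")
  pool
}

#' Select a protocol from a pool, explicitly or uniformly at random
#'
#' @param pool list of \linkS4class{Protocol} (from
#'   \code{\link{loadProtocolPool}})
#' @param name explicit protocol name, or NULL for random selection
#' @param seed RNG seed for random selection (reproducible assignment)
#' @return a \linkS4class{Protocol}
#' @export
selectProtocol <- function(pool, name = NULL, seed = NULL) {
  if (!is.null(name)) {
    nm <- vapply(pool, function(p) p@name, character(1))
    i <- match(name, nm)
    if (is.na(i)) stop("no protocol named '", name, "' in pool")
    return(pool[[i]])
  }
  withSeed(seed, pool[[sample.int(length(pool), 1)]])
}

#' Create a subject folder, never overwriting an existing one
#'
#' Creates \code{root/user_id}; if that folder already exists an incremented
#' suffix is attached: \code{user_id_1}, \code{user_id_2}, ...
#'
#' @param root results root folder (created if missing)
#' @param user_id subject identifier
#' @return the path of the newly created folder
#' @export
createSubjectFolder <- function(root, user_id) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("results root is not writable: ", root)
  path <- file.path(root, user_id)
  k <- 0
  while (dir.exists(path)) {
    k <- k + 1
    path <- file.path(root, sprintf("%s_%d", user_id, k))
  }
  dir.create(path)
  path
}

#' Run a protocol for one subject
#'
#' Executes the protocol's scenes in order, passing each its parameter string
#' and a dedicated output subfolder (one per protocol position, named
#' \code{NN_sceneid}).  Scene callables come from a registry mapping scene
#' ids to functions \code{function(param, out_dir, context)}.  A scriptable
#' control stream replaces interactive keyboard control: one command per
#' scene visit, "run" (default), "skip" (scene marked skipped), "repeat"
#' (scene executed twice, second file set lands in the same subfolder) or
#' "restart" (scene executed, then the protocol restarts from the first
#' scene; honoured once).
#'
#' @param protocol a \linkS4class{Protocol}
#' @param subject_dir subject folder (from \code{\link{createSubjectFolder}})
#' @param registry named list of scene callables
#' @param controls character vector of control commands, consumed one per
#'   scene visit; missing entries default to "run"
#' @param context free-form list passed to every scene callable
#' @return run log data.frame: position, scene id, param, status, out_dir
#' @export
runProtocol <- function(protocol, subject_dir, registry, controls = NULL,
                        context = list()) {
  stopifnot(is(protocol, "Protocol"))
  scenes <- protocol@scenes
  unknown <- setdiff(scenes$id, names(registry))
  if (length(unknown))
    stop("unknown scene id(s) in protocol '", protocol@name, "': ",
         paste(unknown, collapse = ", "))
  log <- list()
  visit <- 0
  restarted <- FALSE
  i <- 1
  while (i <= nrow(scenes)) {
    visit <- visit + 1
    cmd <- if (!is.null(controls) && visit <= length(controls))
      controls[visit] else "run"
    out_dir <- file.path(subject_dir,
                         sprintf("%02d_%s", i, gsub("[^A-Za-z0-9]+", "_",
                                                    scenes$id[i])))
    if (cmd == "skip") {
      log[[length(log) + 1]] <- data.frame(
        position = i, id = scenes$id[i], param = scenes$param[i],
        status = "skipped", out_dir = out_dir, stringsAsFactors = FALSE)
      i <- i + 1
      next
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    n_exec <- if (cmd == "repeat") 2 else 1
    for (k in seq_len(n_exec))
      registry[[scenes$id[i]]](scenes$param[i], out_dir, context)
    log[[length(log) + 1]] <- data.frame(
      position = i, id = scenes$id[i], param = scenes$param[i],
      status = if (cmd == "repeat") "repeated" else "completed",
      out_dir = out_dir, stringsAsFactors = FALSE)
    if (cmd == "restart" && !restarted) {
      restarted <- TRUE
      i <- 1
      next
    }
    i <- i + 1
  }
  do.call(rbind, log)
}

#' Default scene registry for simulated runs
#'
#' Maps the canonical scene ids to package functions: "00 MainMenu" records
#' the subject configuration, "01 Baseline" runs a short ideal-lens block,
#' "02 Experiment" runs a matching-task block whose controller condition is
#' chosen by the scene parameter ("1" gaze_point, "2" depth_mode, "3"
#' manual), and "03 Questionnaire" loads the questionnaire named by the
#' parameter and records (simulated neutral) answers.  Sizes are kept small;
#' override via \code{context} entries (scene, eye, observer, n_trials,
#' rate_hz, questionnaire_dir).
#'
#' @return named list of scene callables for \code{\link{runProtocol}}
#' @export
defaultSceneRegistry <- function() {
  condition_state <- function(param) {
    switch(param,
      "2" = controllerState("depth_mode", foveal_radius_deg = 2),
      "3" = controllerState("manual",
                            events = data.frame(t_s = 0, command_D = 1)),
      controllerState("gaze_point"))
  }
  block_fn <- function(param, out_dir, context, ideal) {
    scene <- context$scene %||% makeOfficeScene(width_px = 128,
                                                height_px = 96)
    eye <- context$eye %||% eyeModel(pupil_mm = 3,
                                     accommodation_amplitude_D = 0)
    observer <- context$observer %||% observerModel()
    lens <- if (ideal) tunableLens(0, 4, rate_D_s = Inf, delay_s = 0)
      else context$lens %||% tunableLens(0, 4, rate_D_s = 10, delay_s = 0.05)
    state <- if (ideal) controllerState("gaze_point")
      else condition_state(param)
    runBlock(context$n_trials %||% 2, scene, eye, lens, state, observer,
             seed = context$seed %||% 1, rate_hz = context$rate_hz %||% 30,
             dt_s = 1 / (context$rate_hz %||% 30), out_dir = out_dir,
             render = isTRUE(context$render))
    invisible(NULL)
  }
  list(
    "00 MainMenu" = function(param, out_dir, context) {
      info <- data.frame(key = c("subject", "protocol_param"),
                         value = c(context$subject %||% "unknown", param),
                         stringsAsFactors = FALSE)
      utils::write.csv(info, timestampedPath(out_dir, "mainmenu"),
                       row.names = FALSE)
      invisible(NULL)
    },
    "01 Baseline" = function(param, out_dir, context)
      block_fn(param, out_dir, context, ideal = TRUE),
    "02 Experiment" = function(param, out_dir, context)
      block_fn(param, out_dir, context, ideal = FALSE),
    "03 Questionnaire" = function(param, out_dir, context) {
      qdir <- context$questionnaire_dir %||%
        system.file("extdata", "questionnaires", package = "focalsim")
      q <- loadQuestionnaire(param, qdir)
      answers <- stats::setNames(
        rep(round(mean(c(q@items$scale_min, q@items$scale_max))),
            nrow(q@items)), q@items$id)
      recordAnswers(q, answers, out_dir)
      invisible(NULL)
    })
}
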