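# shared fixtures and the independent LP oracle

allPairsLocal <- function(n) {
  cbind(i = rep(seq_len(n - 1), times = (n - 1):1),
        j = unlist(lapply(seq_len(n - 1), function(a) (a + 1):n)))
}

# two regions, one unit-capacity edge, single mode R = (1, 0.5)
twoNodeFixture <- function() {
  list(graph = regionGraphFromEdges(c("A", "B"), cbind(1, 2), 1),
       activation = activationMatrix(matrix(c(1, 0.5), 2, 1), "m1",
                                     c("A", "B")),
       config = flowConfig(gamma = 1, rho = 1))
}

# three regions, strong edge (i,j) and weak edge (i,k)
threeNodeFixture <- function() {
  list(graph = regionGraphFromEdges(c("i", "j", "k"),
                                    rbind(c(1, 2), c(1, 3)), c(0.99, 0.01)),
       activation = activationMatrix(matrix(c(1, 0.99, 0), 3, 1), "m1",
                                     c("i", "j", "k")),
       config = flowConfig(gamma = 1, rho = 1))
}

# random small flow instance on a complete floored graph
randomFlowInstance <- function(nMax = 4, mMax = 2, rhoChoices = c(0.1, 1, 10)) {
  repeat {
    n <- sample(2:nMax, 1)
    w <- matrix(0, n, n)
    np <- n * (n - 1) / 2
    w[upper.tri(w)] <- stats::runif(np, 0, 10) * stats::rbinom(np, 1, 0.7)
    w <- w + t(w)
    if (max(w) > 0) break
  }
  M <- sample(seq_len(mMax), 1)
  cfg <- flowConfig(rho = sample(rhoChoices, 1))
  g <- regionGraph(w, labels = paste0("N", seq_len(n)), config = cfg)
  R <- activationMatrix(matrix(stats::runif(n * M, 0, 2) *
                                 stats::rbinom(n * M, 1, 0.8), n, M))
  list(graph = g, activation = R, config = cfg)
}

# independent LP oracle: scipy's HiGHS solver through the python interpreter,
# batched over a list of LPSpec objects; returns optimal objective values
oracleObjectives <- function(lps) {
  spec <- lapply(lps, function(lp) list(
    c = lp@objective,
    A = apply(lp@constraints, 1, identity, simplify = FALSE),
    b = lp@rhs))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(spec, fin, digits = NA, auto_unbox = FALSE)
  code <- sprintf(paste0(
    "import json\n",
    "from scipy.optimize import linprog\n",
    "lps = json.load(open('%s'))\n",
    "out = [linprog(p['c'], A_ub=p['A'], b_ub=p['b'], method='highs')\n",
    "       for p in lps]\n",
    "json.dump([{'fun': (r.fun if r.status == 0 else None),\n",
    "            'status': int(r.status)} for r in out], open('%s', 'w'))\n"),
    fin, fout)
  status <- system2("python", c("-c", shQuote(code)))
  if (status != 0) stop("python oracle failed")
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  if (any(res$status != 0)) stop("oracle reported non-optimal status")
  res$fun
}

phantomSpuriousEdges <- c("P6|P7", "P7|P9", "P8|P9", "P9|P10", "P12|P15")
phantomMissedEdges <- c("P1|P2", "P3|P4", "P15|P16")
phantomCrossingEdges <- c("P5|P7", "P6|P9", "P8|P10", "P9|P12", "P11|P15",
                          "P15|P16")
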