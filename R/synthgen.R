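#' Configuration for the synthetic study region
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' conditions of the Taipei-metropolitan study the package emulates: 1488
#' villages served by 1774 pharmacies over a 49-day rationing window with a
#' quota of nine adult masks per person per two weeks, an overall service
#' rate of 0.033 customers per adult per day, and fixed effects / variance
#' components set to the Poisson-spatial posterior means reported for that
#' system. Tests and the analysis scripts pass smaller `n_villages` /
#' `n_stores` / `n_days` explicitly.
#'
#' @param n_villages number of village polygons (>= 2).
#' @param n_stores number of pharmacies.
#' @param region_size side length of the square study region, metres.
#' @param seed integer; fully determines all generated output.
#' @param quota masks per person per two-week ration period (divisor turning
#'   sales into customers).
#' @param n_days length of the observation window, days.
#' @param restock_prob_per_day probability that a store receives a restock
#'   delivery on a given day.
#' @param restock_bins `"any"` places deliveries uniformly over the day,
#'   `"off_hours"` only outside selling hours (so restocks never share an
#'   hour with sales).
#' @param business_hours opening and closing hour of the selling window.
#' @param service_rate overall customers served per adult per day; sets the
#'   expected counts `E_i = service_rate * pop_i` used as the model offset.
#' @param pop_median,pop_sdlog lognormal parameters for village adult
#'   populations (median on the natural scale).
#' @param income_median,income_sdlog lognormal parameters for village median
#'   annual per-capita income, thousands of NTD.
#' @param mean_store_sales mean adult masks sold per store per day.
#' @param true_coefficients length-7 vector `b0..b6`: intercept, store count,
#'   log(income), business %, residential %, mixed %, school %.
#' @param precision_spatial ICAR precision `1/sigma_u^2`.
#' @param precision_iid unstructured precision `1/sigma_v^2`.
#' @param family `"poisson"` or `"negbin"` for the count draw.
#' @param size_parameter negative-binomial size (overdispersion) parameter;
#'   variance is `lambda + lambda^2 / size`.
#' @param start_date first calendar day of the inventory window.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_villages = 1488,
                         n_stores = 1774,
                         region_size = 50000,
                         seed = 1L,
                         quota = 9L,
                         n_days = 49L,
                         restock_prob_per_day = 0.3,
                         restock_bins = c("any", "off_hours"),
                         business_hours = c(9L, 21L),
                         service_rate = 0.033,
                         pop_median = 4268,
                         pop_sdlog = 0.6,
                         income_median = 439,
                         income_sdlog = 0.25,
                         mean_store_sales = 900,
                         true_coefficients = c(3.702, 0.124, -0.565,
                                               0.559, -2.821, -0.990, 0.467),
                         precision_spatial = 0.497,
                         precision_iid = 6.380,
                         family = c("poisson", "negbin"),
                         size_parameter = 1.6,
                         start_date = as.Date("2020-04-09")) {
  family <- match.arg(family)
  restock_bins <- match.arg(restock_bins)
  stopifnot(
    n_villages >= 2, n_stores >= 1, region_size > 0,
    quota >= 1, n_days >= 1,
    restock_prob_per_day >= 0, restock_prob_per_day <= 1,
    service_rate > 0, precision_spatial > 0, precision_iid > 0,
    length(true_coefficients) == 7,
    business_hours[1] >= 0, business_hours[2] <= 24,
    business_hours[1] < business_hours[2]
  )
  if (family == "negbin" && size_parameter <= 0)
    stop("size_parameter must be > 0 for the negative binomial family")
  structure(list(
    n_villages = as.integer(n_villages), n_stores = as.integer(n_stores),
    region_size = region_size, seed = as.integer(seed),
    quota = as.integer(quota), n_days = as.integer(n_days),
    restock_prob_per_day = restock_prob_per_day,
    restock_bins = restock_bins,
    business_hours = as.integer(business_hours),
    service_rate = service_rate,
    pop_median = pop_median, pop_sdlog = pop_sdlog,
    income_median = income_median, income_sdlog = income_sdlog,
    mean_store_sales = mean_store_sales,
    true_coefficients = true_coefficients,
    precision_spatial = precision_spatial, precision_iid = precision_iid,
    family = family, size_parameter = size_parameter,
    start_date = start_date
  ), class = "synth_config")
}

# One global seed, one named stream per sub-generator: each stream seeds the
# base RNG with a distinct deterministic function of (seed, stream name), so
# regenerating one artefact never perturbs another.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, stream))
  expr
}

#' Generate a synthetic village tessellation with populations and covariates
#'
#' Villages are the Voronoi cells of uniformly random seed points in the
#' square region, so they tile the region exactly and form a connected
#' contiguity graph. Adult populations are lognormal around a configurable
#' median; covariates mimic the marginal shapes seen in the study area:
#' a small-count store covariate, lognormal income, and four land-use
#' fractions drawn as Dirichlet shares (business, residential, mixed, school
#' plus an unmodelled remainder) so their sum never exceeds one.
#'
#' @param cfg a [synth_config()].
#' @return A `village_frame`: list with `$data` (one row per village:
#'   `village_id`, `pop`, `store_n`, `income`, `business`, `residential`,
#'   `mixed`, `school`), `$polygons` (list of vertex matrices) and `$region`
#'   (`c(xmin, xmax, ymin, ymax)`).
#' @export
generate_villages <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_villages < 2) stop("need at least 2 villages")
  n <- cfg$n_villages
  L <- cfg$region_size
  region <- c(0, L, 0, L)
  pts <- with_stream(cfg$seed, "village_points", {
    cbind(stats::runif(n, 0, L), stats::runif(n, 0, L))
  })
  polys <- voronoi_polygons(pts, region)
  dat <- with_stream(cfg$seed, "village_covariates", {
    pop <- stats::rlnorm(n, meanlog = log(cfg$pop_median), sdlog = cfg$pop_sdlog)
    store_n <- pmin(stats::rpois(n, 1.1), 9L)
    income <- stats::rlnorm(n, meanlog = log(cfg$income_median),
                            sdlog = cfg$income_sdlog)
    # Dirichlet shares via independent gammas; last component is the
    # remainder (roads, parks, water) so the four modelled shares sum < 1.
    alpha <- c(business = 0.4, residential = 1.6, mixed = 1.3,
               school = 0.25, other = 4.0)
    g <- matrix(stats::rgamma(n * 5, shape = rep(alpha, each = n)), nrow = n)
    shares <- g / rowSums(g)
    data.frame(
      village_id = sprintf("V%04d", seq_len(n)),
      pop = round(pop),
      store_n = store_n,
      income = income,
      business = shares[, 1], residential = shares[, 2],
      mixed = shares[, 3], school = shares[, 4],
      stringsAsFactors = FALSE
    )
  })
  names(polys) <- dat$village_id
  structure(list(data = dat, polygons = polys, region = region),
            class = "village_frame")
}

# Voronoi cells of a point set clipped to a rectangular window, as a list of
# open vertex-matrix rings in point order.
voronoi_polygons <- function(pts, region) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = region, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  out <- vector("list", nrow(pts))
  for (tl in tiles) {
    out[[tl$ptNum]] <- cbind(tl$x, tl$y)
  }
  out
}

#' @export
print.village_frame <- function(x, ...) {
  cat("village_frame:", nrow(x$data), "villages over a",
      diff(x$region[1:2]) / 1000, "km square\n")
  cat("columns:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Generate synthetic pharmacy locations and sales rates
#'
#' @param cfg a [synth_config()].
#' @return data.frame with `store_id`, `x`, `y` (uniform over the region) and
#'   `daily_sales`, the store's expected adult masks sold per day (lognormal
#'   around `cfg$mean_store_sales`).
#' @export
generate_stores <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_stream(cfg$seed, "stores", {
    n <- cfg$n_stores
    data.frame(
      store_id = sprintf("S%04d", seq_len(n)),
      x = stats::runif(n, 0, cfg$region_size),
      y = stats::runif(n, 0, cfg$region_size),
      daily_sales = stats::rlnorm(n, meanlog = log(cfg$mean_store_sales) - 0.5^2 / 2,
                                  sdlog = 0.5),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate 10-minute inventory traces with a known sales ledger
#'
#' For each store, realized sales per day are Poisson around the store's
#' expected daily sales and are spread multinomially over the 10-minute bins
#' of the selling window; restock deliveries arrive with probability
#' `restock_prob_per_day` per day at a random bin and add a positive jump.
#' The trace is the resulting piecewise-constant stock level on the full
#' 10-minute grid, with the initial stock chosen so stock never goes
#' negative. The realized per-day sales are returned as a ground-truth
#' ledger for oracle tests of the preprocessing stage.
#'
#' @param cfg a [synth_config()].
#' @param stores data.frame with `store_id` (and optionally `daily_sales`).
#' @param daily_sales expected sales per day, recycled across stores;
#'   defaults to `stores$daily_sales`.
#' @return list with `inventory` (store_id, timestamp, stock), `ledger`
#'   (store_id, date, sales: realized ground truth), `restocks`
#'   (store_id, timestamp, amount) and `initial_stock` (the pre-trace stock
#'   level per store, so `initial + restocks - sales = final` exactly).
#' @export
generate_inventory <- function(cfg, stores, daily_sales = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(daily_sales)) daily_sales <- stores$daily_sales
  if (is.null(daily_sales)) stop("daily_sales not given and absent from stores")
  daily_sales <- rep_len(daily_sales, nrow(stores))
  if (any(daily_sales < 0)) stop("daily_sales must be non-negative")

  bins_per_day <- 144L
  open_bin <- cfg$business_hours[1] * 6L + 1L
  close_bin <- cfg$business_hours[2] * 6L
  sell_bins <- open_bin:close_bin
  restock_pool <- if (cfg$restock_bins == "any") seq_len(bins_per_day)
                  else setdiff(seq_len(bins_per_day), sell_bins)
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  grid <- t0 + 600 * (seq_len(cfg$n_days * bins_per_day) - 1L)

  inv <- vector("list", nrow(stores))
  led <- vector("list", nrow(stores))
  rst <- vector("list", nrow(stores))
  ini <- numeric(nrow(stores))
  with_stream(cfg$seed, "inventory", {
    for (s in seq_len(nrow(stores))) {
      sales_day <- stats::rpois(cfg$n_days, daily_sales[s])
      flow <- numeric(cfg$n_days * bins_per_day)
      for (d in seq_len(cfg$n_days)) {
        if (sales_day[d] > 0) {
          alloc <- stats::rmultinom(1, sales_day[d],
                                    rep(1, length(sell_bins)))[, 1]
          idx <- (d - 1L) * bins_per_day + sell_bins
          flow[idx] <- flow[idx] - alloc
        }
      }
      has_restock <- stats::runif(cfg$n_days) < cfg$restock_prob_per_day
      r_ts <- r_amt <- NULL
      for (d in which(has_restock)) {
        bin <- sample(restock_pool, 1L)
        amount <- 50L * (1L + stats::rpois(1, max(daily_sales[s], 1) / 50))
        idx <- (d - 1L) * bins_per_day + bin
        flow[idx] <- flow[idx] + amount
        r_ts <- c(r_ts, idx); r_amt <- c(r_amt, amount)
      }
      cum <- cumsum(flow)
      initial <- max(0, -min(cum)) + 10
      ini[s] <- initial
      inv[[s]] <- data.frame(
        store_id = stores$store_id[s], timestamp = grid,
        stock = initial + cum, stringsAsFactors = FALSE
      )
      led[[s]] <- data.frame(
        store_id = stores$store_id[s],
        date = cfg$start_date + seq_len(cfg$n_days) - 1L,
        sales = sales_day, stringsAsFactors = FALSE
      )
      if (length(r_ts)) {
        rst[[s]] <- data.frame(store_id = stores$store_id[s],
                               timestamp = grid[r_ts], amount = r_amt,
                               stringsAsFactors = FALSE)
      }
    }
  })
  list(inventory = do.call(rbind, inv),
       ledger = do.call(rbind, led),
       restocks = if (length(rst)) do.call(rbind, rst) else
         data.frame(store_id = character(), timestamp = t0[0], amount = integer()),
       initial_stock = data.frame(store_id = stores$store_id,
                                  initial = ini, stringsAsFactors = FALSE))
}

#' Draw a sum-to-zero ICAR field
#'
#' Samples the spatially structured effect from the intrinsic CAR prior with
#' joint precision `(1/sigma2) * (D - A)`. The improper prior is made proper
#' by eigendecomposing `D - A` and dropping its null space (one constant
#' vector per connected component), which enforces a sum-to-zero constraint
#' within every component; islands receive exactly zero.
#'
#' @param adj an [build_adjacency()] object.
#' @param sigma2 conditional variance parameter `sigma_u^2`.
#' @return numeric vector, one effect per area, summing to zero (to numerical
#'   tolerance) within each connected component.
#' @export
sample_icar <- function(adj, sigma2) {
  n <- length(adj$N)
  Q <- -as.matrix(adj$a)
  diag(Q) <- adj$N
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  if (!any(keep)) return(numeric(n))
  V <- e$vectors[, keep, drop = FALSE]
  z <- stats::rnorm(sum(keep))
  drop(V %*% (z / sqrt(e$values[keep]))) * sqrt(sigma2)
}

#' Simulate village supply counts from the spatial count model
#'
#' Draws the structured effect `u` from the ICAR prior, the unstructured
#' effect `v` iid normal, forms the relative risk
#' `rho_i = exp(b0 + x_i' b + u_i + v_i)` and draws counts
#' `Y_i ~ Poisson(E_i rho_i)` or negative binomial with the same mean and
#' size `cfg$size_parameter`. Expected counts are `E_i = service_rate *
#' pop_i`, the demand-side offset.
#'
#' @param frame a `village_frame` from [generate_villages()].
#' @param cfg a [synth_config()] carrying the true parameter values.
#' @param adj optional precomputed [build_adjacency()]; built from the frame
#'   when missing.
#' @return list with `villages` (the frame with `E`, `Y`, `rho_raw` columns
#'   added) and `truth` (coefficients, `u`, `v`, `rho`, `lambda`, `E`).
#' @export
simulate_counts <- function(frame, cfg, adj = NULL) {
  stopifnot(inherits(frame, "village_frame"), inherits(cfg, "synth_config"))
  if (is.null(adj)) adj <- build_adjacency(frame)
  dat <- frame$data
  E <- cfg$service_rate * dat$pop
  if (any(E <= 0)) stop("all expected counts must be positive; check populations")
  X <- village_design(frame)
  b <- cfg$true_coefficients
  out <- with_stream(cfg$seed, "counts", {
    u <- sample_icar(adj, 1 / cfg$precision_spatial)
    v <- stats::rnorm(nrow(dat), 0, sqrt(1 / cfg$precision_iid))
    eta <- drop(X %*% b) + u + v
    rho <- exp(eta)
    lam <- E * rho
    Y <- if (cfg$family == "poisson") {
      stats::rpois(nrow(dat), lam)
    } else {
      stats::rnbinom(nrow(dat), size = cfg$size_parameter, mu = lam)
    }
    list(u = u, v = v, rho = rho, lam = lam, Y = Y)
  })
  dat$E <- E
  dat$Y <- out$Y
  dat$rho_raw <- out$Y / E
  frame$data <- dat
  list(
    villages = frame,
    truth = list(coefficients = b, u = out$u, v = out$v,
                 rho = out$rho, lambda = out$lam, E = E)
  )
}

# Model design matrix in the covariate scale used throughout: store count
# raw, income entering as log(median income), land-use fractions raw.
village_design <- function(frame) {
  d <- frame$data
  cbind(intercept = 1, store_n = d$store_n, log_income = log(d$income),
        business = d$business, residential = d$residential,
        mixed = d$mixed, school = d$school)
}
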