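# Tabular generative adversarial network for virtual-cohort synthesis:
# two-hidden-layer multilayer perceptrons (generator: tanh; discriminator:
# leaky ReLU) trained with the standard minimax (non-saturating) GAN loss
# and Adam, written directly in matrix code. Continuous features are
# standardized, categorical features one-hot encoded with a per-block
# softmax head. A Gaussian-copula generator (empirical marginals + Gaussian
# dependence) serves as the non-adversarial fidelity baseline, and a
# Kolmogorov-Smirnov / total-variation / correlation-gap fidelity report
# validates any synthetic table.

#' GAN configuration
#'
#' @param latent_dim dimension of the generator's noise input.
#' @param generator_layers,discriminator_layers hidden-layer widths.
#' @param epochs training epochs (bounded by design for desk-scale runs).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param moment_weight weight of the feature-matching term added to the
#'   generator loss (squared error of the batch means and centered
#'   covariances of the encoded features); 0 disables it.
#' @param seed training seed.
#' @return A \code{gan_config} list.
#' @export
gan_config <- function(latent_dim = 16, generator_layers = c(64, 64),
                       discriminator_layers = c(64, 64), epochs = 300,
                       batch_size = 512, learning_rate = 5e-4,
                       moment_weight = 3, seed = 1L) {
  stopifnot(latent_dim > 0, all(generator_layers > 0),
            all(discriminator_layers > 0), epochs >= 0, batch_size > 0,
            learning_rate > 0, moment_weight >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 generator_layers = as.integer(generator_layers),
                 discriminator_layers = as.integer(discriminator_layers),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 moment_weight = moment_weight, seed = as.integer(seed)),
            class = "gan_config")
}

# ---- encoding ----------------------------------------------------------

.skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

.encode_schema <- function(table) {
  is_cont <- vapply(table, is.numeric, logical(1))
  cont <- names(table)[is_cont]
  cat <- names(table)[!is_cont]
  levels <- lapply(table[cat], function(x) sort(unique(as.character(x))))
  # strictly positive, right-skewed features are modelled on the log scale
  logged <- vapply(table[cont], function(x)
    all(x > 0) && stats::sd(x) > 0 && .skewness(x) > 1, logical(1))
  tx <- table[cont]
  for (cl in cont[logged]) tx[[cl]] <- log(tx[[cl]])
  list(cont = cont, cat = cat, levels = levels, logged = logged,
       mean = vapply(tx, mean, numeric(1)),
       sd = vapply(tx, function(x) max(stats::sd(x), 1e-12), numeric(1)),
       min = vapply(table[cont], min, numeric(1)),
       max = vapply(table[cont], max, numeric(1)),
       types = vapply(table, function(x) class(x)[1], character(1)),
       order = names(table))
}

.cont_matrix <- function(table, sc) {
  tx <- table[sc$cont]
  for (cl in sc$cont[sc$logged]) tx[[cl]] <- log(tx[[cl]])
  sweep(sweep(as.matrix(tx), 2, sc$mean), 2, sc$sd, "/")
}

.encode_table <- function(table, sc) {
  Xc <- .cont_matrix(table, sc)
  blocks <- lapply(sc$cat, function(cl) {
    lv <- sc$levels[[cl]]
    m <- matrix(0, nrow(table), length(lv))
    m[cbind(seq_len(nrow(table)), match(as.character(table[[cl]]), lv))] <- 1
    m
  })
  cbind(Xc, do.call(cbind, c(blocks, list(matrix(0, nrow(table), 0)))))
}

# softmax over categorical blocks, identity over continuous dims
.output_transform <- function(Y, sc) {
  nc <- length(sc$cont)
  off <- nc
  for (cl in sc$cat) {
    k <- length(sc$levels[[cl]])
    B <- Y[, off + seq_len(k), drop = FALSE]
    B <- exp(B - apply(B, 1, max))
    Y[, off + seq_len(k)] <- B / rowSums(B)
    off <- off + k
  }
  Y
}

# ---- minimal MLP machinery --------------------------------------------

.mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0,
                                 sqrt(2 / sizes[i])), sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

.lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
.lrelu_g <- function(x) ifelse(x > 0, 1, 0.2)

# forward pass storing pre-activations; act = "tanh" or "lrelu";
# final layer is linear
.mlp_forward <- function(layers, X, act) {
  as_ <- list(); hs <- list(X)
  L <- length(layers)
  for (i in seq_len(L)) {
    A <- sweep(hs[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    as_[[i]] <- A
    hs[[i + 1]] <- if (i < L) {
      if (act == "tanh") tanh(A) else .lrelu(A)
    } else A
  }
  list(out = hs[[length(hs)]], as_ = as_, hs = hs)
}

# backward pass: dOut is gradient wrt the linear output
.mlp_backward <- function(layers, fw, dOut, act) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = t(fw$hs[[i]]) %*% delta, b = colSums(delta))
    if (i > 1) {
      dh <- delta %*% t(layers[[i]]$W)
      delta <- if (act == "tanh") dh * (1 - tanh(fw$as_[[i - 1]])^2)
               else dh * .lrelu_g(fw$as_[[i - 1]])
    }
  }
  grads
}

.adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

.adam_step <- function(layers, grads, state, lr, t, b1 = 0.5, b2 = 0.999,
                       eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      m <- state[[i]][[paste0("m", nm)]] <- b1 * state[[i]][[paste0("m", nm)]] + (1 - b1) * g
      v <- state[[i]][[paste0("v", nm)]] <- b2 * state[[i]][[paste0("v", nm)]] + (1 - b2) * g^2
      mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(layers = layers, state = state)
}

# ---- training ----------------------------------------------------------

#' Train the tabular GAN
#'
#' Adversarial training with the standard minimax objective: the
#' discriminator maximizes \code{log D(x) + log(1 - D(G(z)))}, the
#' generator follows the non-saturating \code{-log D(G(z))} gradient. Both
#' networks are updated once per minibatch with Adam. Deterministic given
#' the config seed (up to floating-point library differences).
#'
#' @param table complete covariate data.frame (numeric columns are treated
#'   as continuous, everything else as categorical).
#' @param config a \code{gan_config}.
#' @return A \code{gan_generator} handle (generator weights + schema +
#'   per-epoch loss history). With \code{epochs = 0} the untrained
#'   initialization is returned.
#' @export
fit_generator <- function(table, config = gan_config()) {
  if (anyNA(table)) stop("table must be complete (impute first)")
  sc <- .encode_schema(table)
  X <- .encode_table(table, sc)
  p <- ncol(X)
  .with_seed(config$seed, {
    G <- .mlp_init(c(config$latent_dim, config$generator_layers, p))
    D <- .mlp_init(c(p, config$discriminator_layers, 1))
    stG <- .adam_init(G); stD <- .adam_init(D)
    n <- nrow(X)
    bs <- min(config$batch_size, n)
    loss_d <- loss_g <- numeric(config$epochs)
    t_adam <- 0
    if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ld <- lg <- 0; nb <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1, n)]
        m <- length(idx)
        Xr <- X[idx, , drop = FALSE]
        Z <- matrix(stats::rnorm(m * config$latent_dim), m)
        fwG <- .mlp_forward(G, Z, "tanh")
        Xf <- .output_transform(fwG$out, sc)
        t_adam <- t_adam + 1

        # discriminator step
        fwr <- .mlp_forward(D, Xr, "lrelu")
        fwf <- .mlp_forward(D, Xf, "lrelu")
        pr <- stats::plogis(fwr$out); pf <- stats::plogis(fwf$out)
        ld_b <- -mean(log(pr + 1e-12)) - mean(log(1 - pf + 1e-12))
        gr <- .mlp_backward(D, fwr, (pr - 1) / m, "lrelu")
        gf <- .mlp_backward(D, fwf, pf / m, "lrelu")
        gD <- lapply(seq_along(D), function(i)
          list(W = gr[[i]]$W + gf[[i]]$W, b = gr[[i]]$b + gf[[i]]$b))
        up <- .adam_step(D, gD, stD, config$learning_rate, t_adam)
        D <- up$layers; stD <- up$state

        # generator step (non-saturating loss through the fresh D)
        fwf2 <- .mlp_forward(D, Xf, "lrelu")
        pf2 <- stats::plogis(fwf2$out)
        lg_b <- -mean(log(pf2 + 1e-12))
        dS <- -(1 - pf2) / m
        # gradient wrt D's input
        delta <- dS
        for (i in rev(seq_along(D))) {
          dh <- delta %*% t(D[[i]]$W)
          if (i > 1) delta <- dh * .lrelu_g(fwf2$as_[[i - 1]]) else dX <- dh
        }
        # feature matching: align batch means and second moments
        if (config$moment_weight > 0) {
          # means weighted higher: they carry the categorical frequencies
          dmu <- 2 / m * (colMeans(Xf) - colMeans(Xr))
          Xfc <- sweep(Xf, 2, colMeans(Xf))
          Xrc <- sweep(Xr, 2, colMeans(Xr))
          dC <- 4 / m * (Xfc %*% (crossprod(Xfc) / m - crossprod(Xrc) / m))
          dX <- dX + config$moment_weight *
            (5 * matrix(dmu, m, length(dmu), byrow = TRUE) + dC)
        }
        # through the softmax blocks
        dY <- dX
        off <- length(sc$cont)
        for (cl in sc$cat) {
          k <- length(sc$levels[[cl]])
          cols <- off + seq_len(k)
          S <- Xf[, cols, drop = FALSE]
          dB <- dX[, cols, drop = FALSE]
          dY[, cols] <- S * (dB - rowSums(dB * S))
          off <- off + k
        }
        gG <- .mlp_backward(G, fwG, dY, "tanh")
        up <- .adam_step(G, gG, stG, config$learning_rate, t_adam)
        G <- up$layers; stG <- up$state

        if (!is.finite(ld_b) || !is.finite(lg_b))
          stop("GAN training diverged (non-finite loss) at epoch ", ep)
        ld <- ld + ld_b; lg <- lg + lg_b; nb <- nb + 1
      }
      loss_d[ep] <- ld / nb; loss_g[ep] <- lg / nb
    }
    structure(list(kind = "gan", layers = G, schema = sc, config = config,
                   loss_history = data.frame(epoch = seq_len(config$epochs),
                                             d_loss = loss_d, g_loss = loss_g)),
              class = c("gan_generator", "cohort_generator"))
  })
}

#' Gaussian-copula baseline generator
#'
#' Empirical marginals coupled by the Gaussian dependence of the
#' normal-scores transform; categorical columns are sampled independently
#' from their empirical frequencies. Used as the non-adversarial fidelity
#' baseline the GAN must match or beat on correlation preservation.
#'
#' @param table complete covariate data.frame.
#' @param seed stored as the handle's default sampling seed.
#' @return A \code{copula_generator} handle.
#' @export
copula_baseline <- function(table, seed = 1L) {
  if (anyNA(table)) stop("table must be complete")
  sc <- .encode_schema(table)
  for (cl in sc$cont)
    if (sc$sd[[cl]] <= 1e-11)
      warning("degenerate marginal: column ", cl, " is (near) constant")
  Zs <- vapply(table[sc$cont], function(x) {
    stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
  }, numeric(nrow(table)))
  R <- suppressWarnings(stats::cor(Zs)) # degenerate columns yield NA
  R[is.na(R)] <- 0
  diag(R) <- 1
  freq <- lapply(sc$cat, function(cl)
    table(factor(as.character(table[[cl]]), levels = sc$levels[[cl]])) / nrow(table))
  names(freq) <- sc$cat
  structure(list(kind = "copula", schema = sc, R = R,
                 marginals = lapply(table[sc$cont], sort), freq = freq,
                 seed = as.integer(seed)),
            class = c("copula_generator", "cohort_generator"))
}

#' Sample a synthetic cohort table from a trained generator
#'
#' Continuous features are mapped back to natural units (de-standardized
#' for the GAN, empirical quantiles for the copula) and clipped to the
#' training ranges, which enforces rules such as age >= 18; categorical
#' columns are decoded to valid categories.
#'
#' @param generator a \code{cohort_generator} handle.
#' @param n number of rows (> 0).
#' @param seed sampling seed.
#' @return data.frame with the training schema.
#' @export
sample_cohort <- function(generator, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  n <- as.integer(n)
  sc <- generator$schema
  .with_seed(seed, {
    if (generator$kind == "gan") {
      Z <- matrix(stats::rnorm(n * generator$config$latent_dim), n)
      Y <- .output_transform(.mlp_forward(generator$layers, Z, "tanh")$out, sc)
      out <- list()
      for (i in seq_along(sc$cont)) {
        cl <- sc$cont[i]
        x <- Y[, i] * sc$sd[[cl]] + sc$mean[[cl]]
        if (sc$logged[[cl]]) x <- exp(x)
        out[[cl]] <- pmin(pmax(x, sc$min[[cl]]), sc$max[[cl]])
      }
      off <- length(sc$cont)
      for (cl in sc$cat) {
        k <- length(sc$levels[[cl]])
        P <- Y[, off + seq_len(k), drop = FALSE]
        u <- stats::runif(n)
        cum <- t(apply(P, 1, cumsum))
        pick <- rowSums(cum < u) + 1L # inverse-CDF draw per row
        out[[cl]] <- sc$levels[[cl]][pmin(pick, k)]
        off <- off + k
      }
    } else {
      L <- chol(generator$R + diag(1e-9, ncol(generator$R)))
      Z <- matrix(stats::rnorm(n * ncol(generator$R)), n) %*% L
      U <- stats::pnorm(Z)
      out <- list()
      for (i in seq_along(sc$cont)) {
        cl <- sc$cont[i]
        xs <- generator$marginals[[cl]]
        out[[cl]] <- xs[pmax(1L, ceiling(U[, i] * length(xs)))]
      }
      for (cl in sc$cat)
        out[[cl]] <- sample(sc$levels[[cl]], n, replace = TRUE,
                            prob = as.numeric(generator$freq[[cl]]))
    }
    df <- as.data.frame(out, stringsAsFactors = FALSE)
    for (cl in sc$cat)
      if (sc$types[[cl]] == "logical") df[[cl]] <- as.logical(df[[cl]])
    df[sc$order]
  })
}

# ---- fidelity ----------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = max |ECDF1 - ECDF2| with an asymptotic p-value from the Kolmogorov
#' tail series.
#'
#' @param x,y numeric samples.
#' @return List with \code{D} and \code{p}.
#' @export
ks2_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- sort(unique(c(x, y)))
  e1 <- stats::ecdf(x)(all_v)
  e2 <- stats::ecdf(y)(all_v)
  D <- max(abs(e1 - e2))
  en <- sqrt(n1 * n2 / (n1 + n2))
  lambda <- (en + 0.12 + 0.11 / en) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(max(p, 0), 1))
}

#' Distributional fidelity report for a synthetic table
#'
#' Per continuous feature: two-sample KS statistic against the real table.
#' Per categorical feature: total-variation distance of the category
#' frequencies. Plus the correlation gap: the Frobenius norm of the
#' difference between the real and synthetic Pearson correlation matrices
#' of the continuous features.
#'
#' @param real_table,synthetic_table data.frames with identical schema.
#' @param thresholds list with \code{ks_d}, \code{tv},
#'   \code{correlation_gap} pass thresholds.
#' @return A \code{fidelity_report}: \code{continuous} (feature, D, p,
#'   pass), \code{categorical} (feature, tv, pass),
#'   \code{correlation_gap}, overall \code{pass}.
#' @export
fidelity_report <- function(real_table, synthetic_table,
                            thresholds = list(ks_d = 0.1, tv = 0.05,
                                              correlation_gap = 0.5)) {
  if (!identical(sort(names(real_table)), sort(names(synthetic_table))))
    stop("schema mismatch: tables must share the same columns")
  synthetic_table <- synthetic_table[names(real_table)]
  sc <- .encode_schema(real_table)
  cont <- do.call(rbind, lapply(sc$cont, function(cl) {
    ks <- ks2_stat(real_table[[cl]], synthetic_table[[cl]])
    data.frame(feature = cl, D = ks$D, p = ks$p, pass = ks$D < thresholds$ks_d,
               stringsAsFactors = FALSE)
  }))
  catg <- do.call(rbind, lapply(sc$cat, function(cl) {
    lv <- sort(unique(c(as.character(real_table[[cl]]),
                        as.character(synthetic_table[[cl]]))))
    f1 <- table(factor(as.character(real_table[[cl]]), lv)) / nrow(real_table)
    f2 <- table(factor(as.character(synthetic_table[[cl]]), lv)) / nrow(synthetic_table)
    tv <- sum(abs(f1 - f2)) / 2
    data.frame(feature = cl, tv = tv, pass = tv < thresholds$tv,
               stringsAsFactors = FALSE)
  }))
  gap <- if (length(sc$cont) >= 2) {
    R1 <- stats::cor(real_table[sc$cont])
    R2 <- stats::cor(synthetic_table[sc$cont])
    sqrt(sum((R1 - R2)^2))
  } else 0
  structure(list(continuous = cont, categorical = catg,
                 correlation_gap = gap,
                 thresholds = thresholds,
                 pass = all(cont$pass) &&
                   (is.null(catg) || all(catg$pass)) &&
                   gap < thresholds$correlation_gap),
            class = "fidelity_report")
}

#' Write a fidelity report as JSON
#' @param report a \code{fidelity_report}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fidelity_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
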