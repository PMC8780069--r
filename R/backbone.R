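# Backbone networks. A backbone is a nested spec tree of primitive nodes
# (conv / bn / relu / maxpool / seq / residual); parameters and batch-norm
# buffers live in flat named lists keyed by node path, so the optimizer,
# checkpoint I/O and the parameter-group partition all see one namespace.

node_conv <- function(name, cin, cout, k, stride = 1L, pad = 0L, bias = FALSE) {
  list(type = "conv", name = name, cin = cin, cout = cout, k = k,
       stride = stride, pad = pad, bias = bias)
}
node_bn <- function(name, c) list(type = "bn", name = name, c = c)
node_relu <- function() list(type = "relu")
node_maxpool <- function(k, stride, pad = 0L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
node_seq <- function(...) list(type = "seq", items = list(...))

# residual: out = relu(body(x) + down(x)); down == NULL means identity shortcut
node_residual <- function(body, down = NULL)
  list(type = "residual", body = body, down = down)

bottleneck_block <- function(name, cin, mid, cout, stride = 1L) {
  body <- node_seq(
    node_conv(paste0(name, ".conv1"), cin, mid, 1L),
    node_bn(paste0(name, ".bn1"), mid), node_relu(),
    node_conv(paste0(name, ".conv2"), mid, mid, 3L, stride = stride, pad = 1L),
    node_bn(paste0(name, ".bn2"), mid), node_relu(),
    node_conv(paste0(name, ".conv3"), mid, cout, 1L),
    node_bn(paste0(name, ".bn3"), cout))
  down <- NULL
  if (stride != 1L || cin != cout) {
    down <- node_seq(
      node_conv(paste0(name, ".down.conv"), cin, cout, 1L, stride = stride),
      node_bn(paste0(name, ".down.bn"), cout))
  }
  node_residual(body, down)
}

resnet_stage <- function(name, cin, mid, cout, blocks, stride) {
  items <- vector("list", blocks)
  items[[1]] <- bottleneck_block(paste0(name, ".b1"), cin, mid, cout, stride)
  for (i in seq_len(blocks - 1)) {
    items[[i + 1]] <- bottleneck_block(paste0(name, ".b", i + 1), cout, mid, cout, 1L)
  }
  list(type = "seq", items = items)
}

# 50-layer residual backbone: 7x7/2 stem + max pool, bottleneck stages
# [3, 4, 6, 3], emitting a 7x7x2048 map for 224x224 inputs.
backbone_spec_resnet50 <- function() {
  list(spec = node_seq(
         node_conv("stem.conv", 3L, 64L, 7L, stride = 2L, pad = 3L),
         node_bn("stem.bn", 64L), node_relu(),
         node_maxpool(3L, 2L, pad = 1L),
         resnet_stage("s1", 64L, 64L, 256L, 3L, 1L),
         resnet_stage("s2", 256L, 128L, 512L, 4L, 2L),
         resnet_stage("s3", 512L, 256L, 1024L, 6L, 2L),
         resnet_stage("s4", 1024L, 512L, 2048L, 3L, 2L)),
       out_channels = 2048L, downsample_factor = 32L)
}

# Lightweight test backbone: strided 3x3 conv stages down to a 7x7 map.
# For input_size 56 the stages 3->16->32->32 give a 7x7x32 map, which keeps
# every head shape proportional to the full network.
backbone_spec_tiny <- function(channels = c(16L, 32L, 32L)) {
  items <- list()
  cin <- 3L
  for (i in seq_along(channels)) {
    items <- c(items, list(
      node_conv(sprintf("t%d.conv", i), cin, channels[i], 3L, stride = 2L, pad = 1L),
      node_bn(sprintf("t%d.bn", i), channels[i]), node_relu()))
    cin <- channels[i]
  }
  list(spec = list(type = "seq", items = items),
       out_channels = cin, downsample_factor = as.integer(2^length(channels)))
}

# He-style initialization for convs; unit-gain batch norm.
backbone_init <- function(spec, prefix = "backbone.") {
  params <- list(); buffers <- list()
  walk <- function(nd) {
    switch(nd$type,
      conv = {
        fan_in <- nd$k * nd$k * nd$cin
        params[[paste0(prefix, nd$name, ".w")]] <<-
          array(stats::rnorm(nd$k * nd$k * nd$cin * nd$cout, sd = sqrt(2 / fan_in)),
                c(nd$k, nd$k, nd$cin, nd$cout))
        if (nd$bias) params[[paste0(prefix, nd$name, ".b")]] <<- numeric(nd$cout)
      },
      bn = {
        params[[paste0(prefix, nd$name, ".gamma")]] <<- rep(1, nd$c)
        params[[paste0(prefix, nd$name, ".beta")]] <<- numeric(nd$c)
        buffers[[paste0(prefix, nd$name, ".mean")]] <<- numeric(nd$c)
        buffers[[paste0(prefix, nd$name, ".var")]] <<- rep(1, nd$c)
      },
      seq = for (it in nd$items) walk(it),
      residual = { walk(nd$body); if (!is.null(nd$down)) walk(nd$down) })
    invisible(NULL)
  }
  walk(spec)
  list(params = params, buffers = buffers)
}

# Forward pass through a spec tree. Returns the output, per-node caches (for
# backward) and updated batch-norm buffers.
spec_forward <- function(nd, x, params, buffers, training, prefix = "backbone.",
                         keep_cache = FALSE, path = "r") {
  switch(nd$type,
    conv = {
      w <- params[[paste0(prefix, nd$name, ".w")]]
      b <- params[[paste0(prefix, nd$name, ".b")]]
      r <- conv2d_forward(x, w, b, nd$stride, nd$pad, keep_cache = keep_cache)
      list(out = r$out, caches = stats::setNames(list(r$cache), path),
           buffers = buffers)
    },
    bn = {
      nm <- paste0(prefix, nd$name)
      r <- bn_forward(x, params[[paste0(nm, ".gamma")]], params[[paste0(nm, ".beta")]],
                      buffers[[paste0(nm, ".mean")]], buffers[[paste0(nm, ".var")]],
                      training)
      buffers[[paste0(nm, ".mean")]] <- r$running_mean
      buffers[[paste0(nm, ".var")]] <- r$running_var
      list(out = r$out,
           caches = stats::setNames(list(if (keep_cache) r$cache else NULL), path),
           buffers = buffers)
    },
    relu = {
      r <- relu_forward(x)
      list(out = r$out,
           caches = stats::setNames(list(if (keep_cache) r$cache else NULL), path),
           buffers = buffers)
    },
    maxpool = {
      r <- maxpool_forward(x, nd$k, nd$stride, nd$pad)
      list(out = r$out,
           caches = stats::setNames(list(if (keep_cache) r$cache else NULL), path),
           buffers = buffers)
    },
    seq = {
      caches <- list()
      for (i in seq_along(nd$items)) {
        r <- spec_forward(nd$items[[i]], x, params, buffers, training, prefix,
                          keep_cache, paste0(path, ".", i))
        x <- r$out; buffers <- r$buffers; caches <- c(caches, r$caches)
      }
      list(out = x, caches = caches, buffers = buffers)
    },
    residual = {
      rb <- spec_forward(nd$body, x, params, buffers, training, prefix,
                         keep_cache, paste0(path, ".body"))
      buffers <- rb$buffers
      if (is.null(nd$down)) {
        sh <- x; caches <- rb$caches
      } else {
        rd <- spec_forward(nd$down, x, params, buffers, training, prefix,
                           keep_cache, paste0(path, ".down"))
        buffers <- rd$buffers; sh <- rd$out; caches <- c(rb$caches, rd$caches)
      }
      s <- rb$out + sh
      rr <- relu_forward(s)
      caches[[paste0(path, ".addrelu")]] <- if (keep_cache) rr$cache else NULL
      list(out = rr$out, caches = caches, buffers = buffers)
    })
}

# Backward pass mirroring spec_forward; accumulates parameter gradients into a
# named list and returns the gradient with respect to the input.
spec_backward <- function(nd, dout, params, caches, prefix = "backbone.",
                          path = "r") {
  switch(nd$type,
    conv = {
      w <- params[[paste0(prefix, nd$name, ".w")]]
      r <- conv2d_backward(dout, w, caches[[path]])
      g <- stats::setNames(list(r$dw), paste0(prefix, nd$name, ".w"))
      if (!is.null(r$db)) g[[paste0(prefix, nd$name, ".b")]] <- r$db
      list(dx = r$dx, grads = g)
    },
    bn = {
      nm <- paste0(prefix, nd$name)
      r <- bn_backward(dout, params[[paste0(nm, ".gamma")]], caches[[path]])
      list(dx = r$dx,
           grads = stats::setNames(list(r$dgamma, r$dbeta),
                                   c(paste0(nm, ".gamma"), paste0(nm, ".beta"))))
    },
    relu = list(dx = relu_backward(dout, caches[[path]]), grads = list()),
    maxpool = list(dx = maxpool_backward(dout, caches[[path]]), grads = list()),
    seq = {
      grads <- list()
      for (i in rev(seq_along(nd$items))) {
        r <- spec_backward(nd$items[[i]], dout, params, caches, prefix,
                           paste0(path, ".", i))
        dout <- r$dx
        grads <- accumulate_grads(grads, r$grads)
      }
      list(dx = dout, grads = grads)
    },
    residual = {
      ds <- relu_backward(dout, caches[[paste0(path, ".addrelu")]])
      rb <- spec_backward(nd$body, ds, params, caches, prefix,
                          paste0(path, ".body"))
      grads <- rb$grads
      if (is.null(nd$down)) {
        dx <- rb$dx + ds
      } else {
        rd <- spec_backward(nd$down, ds, params, caches, prefix,
                            paste0(path, ".down"))
        grads <- accumulate_grads(grads, rd$grads)
        dx <- rb$dx + rd$dx
      }
      list(dx = dx, grads = grads)
    })
}

accumulate_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
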