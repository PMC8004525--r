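# Randomized steady-state ensemble, second shipped draw (different seed,
# otherwise identical study conditions).
life_history:
  fox: {lifespan: 3.5, annual_factor: 3, capacity: 1}
  cottontail: {lifespan: 1.25, annual_factor: 4.5, capacity: 100}
  hare: {lifespan: 5.5, annual_factor: 5, capacity: 30}
e: 0.91
a: 0.2
b: 0.5
init: [0.4, 1, 3]
n: 500
semiwidth: 0.09
seed: 2
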