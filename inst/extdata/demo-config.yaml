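# End-to-end demonstration run: synthetic two-state loop, zero-temperature
# string on the Mueller-Brown surface, finite-temperature string in Cartesian
# CVs, well-tempered metadynamics on a tilted double well with free-energy
# reconstruction, and ensemble analysis of the synthetic pool.
seed: 2024
outdir: pathdyn-demo
stages: [synth, zts, string, metad, fes, cluster, network, density, rmsf, drive]

system:
  kind: mueller-brown
  temperature: 300
  friction: 10
  timestep: 0.0005

cvs:
  - kind: cartesian
    particle: 1
    dim: 1
  - kind: cartesian
    particle: 1
    dim: 2

synth:
  n_beads: 12
  n_frames: 60
  noise: 0.4

zts:
  endpoints:
    - [-0.5582236, 1.4417258]
    - [0.6234994, 0.0280376]
  start_images: 4
  final_images: 32
  iterations: 40
  descent_steps: 20
  extract: 16
  step_size: 1.0e-4

string:
  k: 2000
  dt: 5.0e-4
  stride: 10
  burnin: 50
  max_iter: 25
  window: 10
  tolerance: 0.01
  final_steps: 300

metad:
  system:
    kind: double-well-1d
    barrier: 2
    tilt: 1
    temperature: 300
    friction: 2
    timestep: 0.01
  cvs:
    - kind: cartesian
      particle: 1
      dim: 1
  height: 0.7
  width: 0.1
  stride: 200
  bias_temperature: 4200
  n_walkers: 4
  steps: 6000
  grid_ranges:
    - [-2.5, 2.5]
  grid_spacing: 0.002

fes:
  grid_spacing: 0.002

cluster:
  diameter: 3.0

network:
  link: 3.8

density:
  nbins: 40
  interval: 0.005

rmsf:
  superpose: false

drive:
  system:
    kind: bead-chain
    n_beads: 4
    bond_length: 3.8
    k_bond: 20
    double_well_bond:
      pair: [1, 2]
      barrier: 5
      minima: [3, 6]
    temperature: 0
  pair1: [1, 2]
  pair2: [2, 3]
  pair3: [3, 4]
  k: 50
  targets: [-4.5, -4.2, -3.9, -3.6, -3.3, -3.0, -2.7, -2.4, -2.1, -1.8]
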