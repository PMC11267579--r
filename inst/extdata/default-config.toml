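# Default simulation and training protocol.
# Units: nm, ps, kJ/mol, u, e, K, bar.

[field]
# particle-mesh grid for a ~5 x 5 x 8 nm membrane patch
grid = [20, 20, 30]
# density of one coarse-grained particle (nm^-3)
rho0 = 8.33
# compressibility controlling local density fluctuations (kJ^-1 mol)
kappa = 0.05
# calibration density: tune so the average density is correct at the
# target temperature and pressure (nm^-3)
a = 9.21
# Gaussian filter spread defining the particle size (nm)
sigma = 0.5
# relative permittivity of the smeared-charge electrostatics
epsr = 15.0
coulomb = false
# assignment window: 2 = cloud-in-cell, 3 = quadratic spline (continuous
# exact-gradient forces; preferred for long constant-energy runs)
order = 2

[run]
# inner (bonded) and outer (field + electrostatic) rRESPA time steps
dt_inner = 0.02
dt_outer = 0.1
temperature = 323.0
# velocity-rescaling and Berendsen coupling times
tau_t = 0.1
pressure = 1.0
tau_p = 0.1
barostat = "off"
# isothermal compressibility used by the barostat (bar^-1)
beta_c = 4.5e-05
n_equil = 2000
n_traced = 200
stride = 1
seed = 1

[loss]
# density-profile weight (nm^6), area-per-lipid weight (nm^-4) and the
# cubic confinement boundary for the mixing parameters (kJ/mol)
w_t = 1.0
w_A = 100.0
dchi_max = 300.0
center = true

[prs]
# independent replicas per loss evaluation; each runs n_equil untraced
# steps followed by n_traced differentiable steps
n_replicas = 40
n_equil = 2000
n_traced = 200
stride = 1
max_failures = 0.1

[optimizer]
# adaptive belief-style update
eta = 0.01
b1 = 0.1
b2 = 0.4
epochs = 600
eps = 1e-12
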