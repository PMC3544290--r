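# Constant parameters for diagnostic calculations, adult humans.
# Format: symbol = value [unit]; decimal commas are accepted.
beta_loglin  = -0.1345          # per pmol/L FT4, log-linear TSH model
alpha_T      = 0,1     1/L      # dilution factor for T4
beta_T       = 1.1e-6  1/s      # clearance exponent for T4
D_T          = 2,75    mU/L     # EC50 of TSH at the thyroid
K41          = 2e10    L/mol    # T4-TBG association constant
K42          = 2e8     L/mol    # T4-TBPA association constant
alpha_31     = 0,026   1/L      # dilution factor for T3
beta_31      = 8e-6    1/s      # clearance exponent for T3
K_M1         = 5e-7    mol/L    # Michaelis constant, type 1 deiodinase
K30          = 2e9     L/mol    # T3-TBG association constant
tshi_mean    = 2.7              # TSH index standardisation mean
tshi_sd      = 0.676            # TSH index standardisation SD
TBG_default  = 3e-7    mol/L    # standard plasma TBG
TBPA_default = 4.5e-6  mol/L    # standard plasma transthyretin
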