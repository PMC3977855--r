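# Doubtful Sound bottlenose dolphin social network (Lusseau et al. 2003)
# 62 nodes, 159 undirected edges; canonical public copy
Beak Fish
Beak Grin
Beak Haecksel
Beak SN9
Beak SN96
Beak TR77
Beescratch Jet
Beescratch Knit
Beescratch Notch
Beescratch Number1
Beescratch Oscar
Beescratch SN100
Beescratch SN90
Beescratch Upbang
Bumper Fish
Bumper SN96
Bumper Thumper
Bumper Zipfel
CCL Double
CCL Grin
CCL Zap
Cross Trigger
DN16 Feather
DN16 Gallatin
DN16 Wave
DN16 Web
DN21 Feather
DN21 Gallatin
DN21 Jet
DN21 Upbang
DN21 Wave
DN21 Web
DN63 Knit
DN63 Number1
DN63 PL
DN63 SN9
DN63 Upbang
Double Kringel
Double Oscar
Double SN4
Double Topless
Double Zap
Feather Gallatin
Feather Jet
Feather Ripplefluke
Feather SN90
Feather Web
Fish Patchback
Fish SN96
Fish TR77
Five Trigger
Fork Scabs
Gallatin Jet
Gallatin Ripplefluke
Gallatin SN90
Gallatin Upbang
Gallatin Web
Grin Hook
Grin MN83
Grin SN4
Grin SN63
Grin SN9
Grin Scabs
Grin Shmuddel
Grin Stripes
Grin TR99
Grin TSN103
Haecksel Jonah
Haecksel MN83
Haecksel SN9
Haecksel Topless
Haecksel Vau
Haecksel Zap
Hook Kringel
Hook SN4
Hook SN63
Hook Scabs
Hook TR99
Jet MN23
Jet Mus
Jet Number1
Jet Quasi
Jet Web
Jonah Kringel
Jonah MN105
Jonah MN83
Jonah Patchback
Jonah Topless
Jonah Trigger
Knit PL
Knit Upbang
Kringel Oscar
Kringel SN100
Kringel SN63
Kringel TR77
Kringel TR99
Kringel Thumper
MN105 Patchback
MN105 SN4
MN105 Scabs
MN105 Topless
MN105 Trigger
MN60 SN100
MN60 Topless
MN60 Trigger
MN83 Patchback
MN83 Topless
MN83 Trigger
Mus Notch
Mus Number1
Notch Number1
Oscar PL
Oscar TR77
PL SN96
PL TR77
Patchback SMN5
Patchback Stripes
Patchback TSN103
Patchback Topless
Patchback Trigger
Ripplefluke Zig
SN100 SN4
SN100 SN89
SN100 SN9
SN100 Zap
SN4 SN9
SN4 Scabs
SN4 Shmuddel
SN4 Stripes
SN4 Topless
SN4 Zipfel
SN63 Scabs
SN63 Stripes
SN63 TSN103
SN63 Thumper
SN63 Whitetip
SN89 Web
SN9 Scabs
SN9 TSN103
SN90 Upbang
SN90 Web
SN96 TR77
SN96 TR99
Scabs Shmuddel
Scabs Stripes
Scabs TR99
Shmuddel TR88
Shmuddel Thumper
Stripes TR120
Stripes TSN83
TR120 TR88
TR82 Web
TR99 Topless
TR99 Trigger
TSN83 Zipfel
Topless Trigger
Topless Zap
Trigger Vau
Upbang Web
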