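source,congener,phase,ng_per_unit
smoking,Nap,particle,75
smoking,Acy,particle,15
smoking,Ace,particle,3
smoking,Fluo,particle,6
smoking,Phe,particle,15
smoking,Ant,particle,2.25
smoking,Flu,particle,7.5
smoking,Pyr,particle,6
smoking,Chry,particle,18
smoking,BaA,particle,15
smoking,BbF,particle,36
smoking,BkF,particle,18
smoking,BaP,particle,30
smoking,DBA,particle,9
smoking,IP,particle,24
smoking,BghiP,particle,27
smoking,Nap,gas,1425
smoking,Acy,gas,285
smoking,Ace,gas,57
smoking,Fluo,gas,114
smoking,Phe,gas,285
smoking,Ant,gas,42.75
smoking,Flu,gas,142.5
smoking,Pyr,gas,114
smoking,Chry,gas,18
smoking,BaA,gas,15
smoking,BbF,gas,0
smoking,BkF,gas,0
smoking,BaP,gas,0
smoking,DBA,gas,0
smoking,IP,gas,0
smoking,BghiP,gas,0
cooking_coal,Nap,particle,75000
cooking_coal,Acy,particle,15000
cooking_coal,Ace,particle,3000
cooking_coal,Fluo,particle,6000
cooking_coal,Phe,particle,15000
cooking_coal,Ant,particle,2250
cooking_coal,Flu,particle,7500
cooking_coal,Pyr,particle,6000
cooking_coal,Chry,particle,18000
cooking_coal,BaA,particle,15000
cooking_coal,BbF,particle,36000
cooking_coal,BkF,particle,18000
cooking_coal,BaP,particle,30000
cooking_coal,DBA,particle,9000
cooking_coal,IP,particle,24000
cooking_coal,BghiP,particle,27000
cooking_coal,Nap,gas,1425000
cooking_coal,Acy,gas,285000
cooking_coal,Ace,gas,57000
cooking_coal,Fluo,gas,114000
cooking_coal,Phe,gas,285000
cooking_coal,Ant,gas,42750
cooking_coal,Flu,gas,142500
cooking_coal,Pyr,gas,114000
cooking_coal,Chry,gas,18000
cooking_coal,BaA,gas,15000
cooking_coal,BbF,gas,0
cooking_coal,BkF,gas,0
cooking_coal,BaP,gas,0
cooking_coal,DBA,gas,0
cooking_coal,IP,gas,0
cooking_coal,BghiP,gas,0
cooking_biomass,Nap,particle,6250
cooking_biomass,Acy,particle,1250
cooking_biomass,Ace,particle,250
cooking_biomass,Fluo,particle,500
cooking_biomass,Phe,particle,1250
cooking_biomass,Ant,particle,187.5
cooking_biomass,Flu,particle,625
cooking_biomass,Pyr,particle,500
cooking_biomass,Chry,particle,1500
cooking_biomass,BaA,particle,1250
cooking_biomass,BbF,particle,3000
cooking_biomass,BkF,particle,1500
cooking_biomass,BaP,particle,2500
cooking_biomass,DBA,particle,750
cooking_biomass,IP,particle,2000
cooking_biomass,BghiP,particle,2250
cooking_biomass,Nap,gas,118750
cooking_biomass,Acy,gas,23750
cooking_biomass,Ace,gas,4750
cooking_biomass,Fluo,gas,9500
cooking_biomass,Phe,gas,23750
cooking_biomass,Ant,gas,3562.5
cooking_biomass,Flu,gas,11875
cooking_biomass,Pyr,gas,9500
cooking_biomass,Chry,gas,1500
cooking_biomass,BaA,gas,1250
cooking_biomass,BbF,gas,0
cooking_biomass,BkF,gas,0
cooking_biomass,BaP,gas,0
cooking_biomass,DBA,gas,0
cooking_biomass,IP,gas,0
cooking_biomass,BghiP,gas,0
cooking_lpg,Nap,particle,250
cooking_lpg,Acy,particle,50
cooking_lpg,Ace,particle,10
cooking_lpg,Fluo,particle,20
cooking_lpg,Phe,particle,50
cooking_lpg,Ant,particle,7.5
cooking_lpg,Flu,particle,25
cooking_lpg,Pyr,particle,20
cooking_lpg,Chry,particle,60
cooking_lpg,BaA,particle,50
cooking_lpg,BbF,particle,120
cooking_lpg,BkF,particle,60
cooking_lpg,BaP,particle,100
cooking_lpg,DBA,particle,30
cooking_lpg,IP,particle,80
cooking_lpg,BghiP,particle,90
cooking_lpg,Nap,gas,4750
cooking_lpg,Acy,gas,950
cooking_lpg,Ace,gas,190
cooking_lpg,Fluo,gas,380
cooking_lpg,Phe,gas,950
cooking_lpg,Ant,gas,142.5
cooking_lpg,Flu,gas,475
cooking_lpg,Pyr,gas,380
cooking_lpg,Chry,gas,60
cooking_lpg,BaA,gas,50
cooking_lpg,BbF,gas,0
cooking_lpg,BkF,gas,0
cooking_lpg,BaP,gas,0
cooking_lpg,DBA,gas,0
cooking_lpg,IP,gas,0
cooking_lpg,BghiP,gas,0
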