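"name","family","units","description"
"TotalRootLength","legacy","cm","Sum of skeleton edge lengths"
"NumberOfTips","legacy","count","Skeleton voxels of 26-neighbor degree <= 1"
"NumberOfEdges","legacy","count","Skeleton graph edges after spur pruning"
"NumberBifurcatingClusters","legacy","count","Clusters of junction voxels within the merge radius"
"AvgSizeBifClusters","legacy","voxel","Mean junction voxels per bifurcating cluster"
"AvgEdgeLength","legacy","cm","Total root length divided by edge count"
"AvgRootRadius","legacy","mm","Mean distance-transform radius along the skeleton"
"SpecificRootLength","legacy","cm/cm3","Total root length per unit root volume"
"Volume","legacy","cm3","Root voxel count times voxel volume"
"SurfaceArea","legacy","cm2","Calibrated local-configuration surface area"
"ConvexHullVolume","legacy","cm3","Volume of the 3D convex hull of root voxel cells"
"Solidity","legacy","dimensionless","Volume / ConvexHullVolume"
"Depth","legacy","cm","Occupied vertical extent"
"HorEqDiameter","legacy","cm","Diameter of circle matching the maximal horizontal convex slice area"
"Elongation","legacy","dimensionless","Depth / HorEqDiameter"
"WidthDepthRatio","legacy","dimensionless","HorEqDiameter / Depth"
"Bushiness","legacy","dimensionless","MaxRootCount / MedianRootCount"
"MaxRootCount","legacy","count","Maximum per-slice 8-connected component count"
"MedianRootCount","legacy","count","Median per-slice 8-connected component count over nonempty slices"
"FractalDimensionSide","fractal","dimensionless","Box-counting dimension of the side (along-y) projection"
"FractalDimensionTop","fractal","dimensionless","Box-counting dimension of the top (along-z) projection"
"BiomassMean","distribution","dimensionless","Biomass vertical profile: Profile mean slab index"
"BiomassStd","distribution","dimensionless","Biomass vertical profile: Profile standard deviation"
"BiomassSkewness","distribution","dimensionless","Biomass vertical profile: Third standardized moment"
"BiomassKurtosis","distribution","dimensionless","Biomass vertical profile: Fourth standardized moment"
"BiomassEnergy","distribution","dimensionless","Biomass vertical profile: Sum of squared normalized profile"
"BiomassEntropy","distribution","dimensionless","Biomass vertical profile: Shannon entropy (bits)"
"BiomassSmoothness","distribution","dimensionless","Biomass vertical profile: 1 - 1/(1 + var of normalized profile)"
"ConvexHullMean","distribution","dimensionless","ConvexHull vertical profile: Profile mean slab index"
"ConvexHullStd","distribution","dimensionless","ConvexHull vertical profile: Profile standard deviation"
"ConvexHullSkewness","distribution","dimensionless","ConvexHull vertical profile: Third standardized moment"
"ConvexHullKurtosis","distribution","dimensionless","ConvexHull vertical profile: Fourth standardized moment"
"ConvexHullEnergy","distribution","dimensionless","ConvexHull vertical profile: Sum of squared normalized profile"
"ConvexHullEntropy","distribution","dimensionless","ConvexHull vertical profile: Shannon entropy (bits)"
"ConvexHullSmoothness","distribution","dimensionless","ConvexHull vertical profile: 1 - 1/(1 + var of normalized profile)"
"SolidityMean","distribution","dimensionless","Solidity vertical profile: Profile mean slab index"
"SolidityStd","distribution","dimensionless","Solidity vertical profile: Profile standard deviation"
"SoliditySkewness","distribution","dimensionless","Solidity vertical profile: Third standardized moment"
"SolidityKurtosis","distribution","dimensionless","Solidity vertical profile: Fourth standardized moment"
"SolidityEnergy","distribution","dimensionless","Solidity vertical profile: Sum of squared normalized profile"
"SolidityEntropy","distribution","dimensionless","Solidity vertical profile: Shannon entropy (bits)"
"SoliditySmoothness","distribution","dimensionless","Solidity vertical profile: 1 - 1/(1 + var of normalized profile)"
"SolidityVHist01","vhist","dimensionless","Solidity of vertical slab 1 of 20 (top to bottom)"
"SolidityVHist02","vhist","dimensionless","Solidity of vertical slab 2 of 20 (top to bottom)"
"SolidityVHist03","vhist","dimensionless","Solidity of vertical slab 3 of 20 (top to bottom)"
"SolidityVHist04","vhist","dimensionless","Solidity of vertical slab 4 of 20 (top to bottom)"
"SolidityVHist05","vhist","dimensionless","Solidity of vertical slab 5 of 20 (top to bottom)"
"SolidityVHist06","vhist","dimensionless","Solidity of vertical slab 6 of 20 (top to bottom)"
"SolidityVHist07","vhist","dimensionless","Solidity of vertical slab 7 of 20 (top to bottom)"
"SolidityVHist08","vhist","dimensionless","Solidity of vertical slab 8 of 20 (top to bottom)"
"SolidityVHist09","vhist","dimensionless","Solidity of vertical slab 9 of 20 (top to bottom)"
"SolidityVHist10","vhist","dimensionless","Solidity of vertical slab 10 of 20 (top to bottom)"
"SolidityVHist11","vhist","dimensionless","Solidity of vertical slab 11 of 20 (top to bottom)"
"SolidityVHist12","vhist","dimensionless","Solidity of vertical slab 12 of 20 (top to bottom)"
"SolidityVHist13","vhist","dimensionless","Solidity of vertical slab 13 of 20 (top to bottom)"
"SolidityVHist14","vhist","dimensionless","Solidity of vertical slab 14 of 20 (top to bottom)"
"SolidityVHist15","vhist","dimensionless","Solidity of vertical slab 15 of 20 (top to bottom)"
"SolidityVHist16","vhist","dimensionless","Solidity of vertical slab 16 of 20 (top to bottom)"
"SolidityVHist17","vhist","dimensionless","Solidity of vertical slab 17 of 20 (top to bottom)"
"SolidityVHist18","vhist","dimensionless","Solidity of vertical slab 18 of 20 (top to bottom)"
"SolidityVHist19","vhist","dimensionless","Solidity of vertical slab 19 of 20 (top to bottom)"
"SolidityVHist20","vhist","dimensionless","Solidity of vertical slab 20 of 20 (top to bottom)"
"DensityS1","density","dimensionless","Root fraction of radial shell 1 of 9 (axis outward)"
"DensityS2","density","dimensionless","Root fraction of radial shell 2 of 9 (axis outward)"
"DensityS3","density","dimensionless","Root fraction of radial shell 3 of 9 (axis outward)"
"DensityS4","density","dimensionless","Root fraction of radial shell 4 of 9 (axis outward)"
"DensityS5","density","dimensionless","Root fraction of radial shell 5 of 9 (axis outward)"
"DensityS6","density","dimensionless","Root fraction of radial shell 6 of 9 (axis outward)"
"DensityS7","density","dimensionless","Root fraction of radial shell 7 of 9 (axis outward)"
"DensityS8","density","dimensionless","Root fraction of radial shell 8 of 9 (axis outward)"
"DensityS9","density","dimensionless","Root fraction of radial shell 9 of 9 (axis outward)"
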