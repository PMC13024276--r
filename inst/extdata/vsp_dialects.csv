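dialect,alias,canonical
v1_8,Particle ID,Id
v1_8,Source Image,SourceImage
v1_8,Capture X,CaptureX
v1_8,Capture Y,CaptureY
v1_8,Collage File,CollageFile
v1_8,Image X,ImageX
v1_8,Image Y,ImageY
v1_8,Image Width,ImageW
v1_8,Image Height,ImageH
v1_8,Calibration Factor,CalibrationFactor
v1_8,Edge Gradient,EdgeGradient
v1_8,ABD Area,AbdArea
v1_8,ABD Diameter,AbdDiameter
v1_8,Average Blue,AvgBlue
v1_8,Average Green,AvgGreen
v1_8,Average Red,AvgRed
v1_8,Intensity,Intensity
v1_8,Length,Length
v1_8,Width,Width
v1_8,Perimeter,Perimeter
v1_8,Roughness,Roughness
v1_8,Sigma Intensity,SigmaIntensity
v1_8,Transparency,Transparency
v2_2,Particle ID,Id
v2_2,Source Image,SourceImage
v2_2,Src X,CaptureX
v2_2,Src Y,CaptureY
v2_2,Collage File,CollageFile
v2_2,Image X,ImageX
v2_2,Image Y,ImageY
v2_2,Image Width,ImageW
v2_2,Image Height,ImageH
v2_2,Calibration Factor,CalibrationFactor
v2_2,Edge Gradient,EdgeGradient
v2_2,ABD Area,AbdArea
v2_2,ABD Diameter,AbdDiameter
v2_2,Average Blue,AvgBlue
v2_2,Average Green,AvgGreen
v2_2,Average Red,AvgRed
v2_2,Intensity,Intensity
v2_2,Length,Length
v2_2,Width,Width
v2_2,Perimeter,Perimeter
v2_2,Roughness,Roughness
v2_2,Sigma Intensity,SigmaIntensity
v2_2,Transparency,Transparency
v2_4,Particle ID,Id
v2_4,Source Image,SourceImage
v2_4,Src X,CaptureX
v2_4,Src Y,CaptureY
v2_4,Collage File,CollageFile
v2_4,Image X,ImageX
v2_4,Image Y,ImageY
v2_4,Image Width,ImageW
v2_4,Image Height,ImageH
v2_4,Calibration Factor,CalibrationFactor
v2_4,Edge Gradient,EdgeGradient
v2_4,Area (ABD),AbdArea
v2_4,Diameter (ABD),AbdDiameter
v2_4,Average Blue,AvgBlue
v2_4,Average Green,AvgGreen
v2_4,Average Red,AvgRed
v2_4,Intensity,Intensity
v2_4,Length,Length
v2_4,Width,Width
v2_4,Perimeter,Perimeter
v2_4,Roughness,Roughness
v2_4,Sigma Intensity,SigmaIntensity
v2_4,Transparency,Transparency
v4_15,Capture ID,Id
v4_15,Source Image,SourceImage
v4_15,Capture X,CaptureX
v4_15,Capture Y,CaptureY
v4_15,Filename,CollageFile
v4_15,Image X,ImageX
v4_15,Image Y,ImageY
v4_15,Image Width,ImageW
v4_15,Image Height,ImageH
v4_15,Calibration Factor,CalibrationFactor
v4_15,Edge Gradient,EdgeGradient
v4_15,Area (ABD),AbdArea
v4_15,Diameter (ABD),AbdDiameter
v4_15,Average Blue,AvgBlue
v4_15,Average Green,AvgGreen
v4_15,Average Red,AvgRed
v4_15,Intensity,Intensity
v4_15,Length,Length
v4_15,Width,Width
v4_15,Perimeter,Perimeter
v4_15,Roughness,Roughness
v4_15,Sigma Intensity,SigmaIntensity
v4_15,Transparency,Transparency
v4_19,Capture ID,Id
v4_19,Source Image,SourceImage
v4_19,Capture X,CaptureX
v4_19,Capture Y,CaptureY
v4_19,Filename,CollageFile
v4_19,Image X,ImageX
v4_19,Image Y,ImageY
v4_19,Image Width,ImageW
v4_19,Image Height,ImageH
v4_19,Calibration Factor,CalibrationFactor
v4_19,Edge Gradient,EdgeGradient
v4_19,Area (ABD),AbdArea
v4_19,Diameter (ABD),AbdDiameter
v4_19,Avg Blue,AvgBlue
v4_19,Avg Green,AvgGreen
v4_19,Avg Red,AvgRed
v4_19,Intensity,Intensity
v4_19,Length,Length
v4_19,Width,Width
v4_19,Perimeter,Perimeter
v4_19,Roughness,Roughness
v4_19,Sigma Intensity,SigmaIntensity
v4_19,Transparency,Transparency
v6_0,UUID,Id
v6_0,SrcImage,SourceImage
v6_0,SrcX,CaptureX
v6_0,SrcY,CaptureY
v6_0,ImageFilename,CollageFile
v6_0,CropX,ImageX
v6_0,CropY,ImageY
v6_0,CropWidth,ImageW
v6_0,CropHeight,ImageH
v6_0,Calibration,CalibrationFactor
v6_0,EdgeGradient,EdgeGradient
v6_0,AreaAbd,AbdArea
v6_0,DiameterAbd,AbdDiameter
v6_0,AvgBlue,AvgBlue
v6_0,AvgGreen,AvgGreen
v6_0,AvgRed,AvgRed
v6_0,Intensity,Intensity
v6_0,Length,Length
v6_0,Width,Width
v6_0,Perimeter,Perimeter
v6_0,Roughness,Roughness
v6_0,SigmaIntensity,SigmaIntensity
v6_0,Transparency,Transparency
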