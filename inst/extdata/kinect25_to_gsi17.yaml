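# Kinect-v2 (25 joints) -> unified 17-keypoint layout.
# All 17 keypoints map directly; hand/foot extremities are discarded.
# Kinect's z axis points away from the camera, so the converter negates z to
# reach the internal convention (x right, y up, z toward camera).
axis_flip_z: true
direct:
  head: Head
  neck: Neck
  shoulder_center: SpineShoulder
  spine_center: SpineMid
  hip_center: SpineBase
  l_shoulder: ShoulderLeft
  r_shoulder: ShoulderRight
  l_elbow: ElbowLeft
  r_elbow: ElbowRight
  l_wrist: WristLeft
  r_wrist: WristRight
  l_hip: HipLeft
  r_hip: HipRight
  l_knee: KneeLeft
  r_knee: KneeRight
  l_ankle: AnkleLeft
  r_ankle: AnkleRight
midpoints: {}
discarded:
  - HandLeft
  - HandRight
  - HandTipLeft
  - HandTipRight
  - ThumbLeft
  - ThumbRight
  - FootLeft
  - FootRight
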