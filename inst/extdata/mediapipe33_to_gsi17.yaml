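# MediaPipe pose (33 landmarks) -> unified 17-keypoint layout.
# Limb joints and the nose (used as head) map directly; the four central-axis
# keypoints are midpoints, resolved in order (entries may reference keypoints
# already produced). Facial, hand and foot landmarks are discarded.
axis_flip_z: false
direct:
  head: nose
  l_shoulder: left_shoulder
  r_shoulder: right_shoulder
  l_elbow: left_elbow
  r_elbow: right_elbow
  l_wrist: left_wrist
  r_wrist: right_wrist
  l_hip: left_hip
  r_hip: right_hip
  l_knee: left_knee
  r_knee: right_knee
  l_ankle: left_ankle
  r_ankle: right_ankle
midpoints:
  shoulder_center: [l_shoulder, r_shoulder]
  hip_center: [l_hip, r_hip]
  spine_center: [shoulder_center, hip_center]
  neck: [head, shoulder_center]
discarded:
  - left_eye_inner
  - left_eye
  - left_eye_outer
  - right_eye_inner
  - right_eye
  - right_eye_outer
  - left_ear
  - right_ear
  - mouth_left
  - mouth_right
  - left_pinky
  - right_pinky
  - left_index
  - right_index
  - left_thumb
  - right_thumb
  - left_heel
  - right_heel
  - left_foot_index
  - right_foot_index
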